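#' Generate territory-structured focal lesion masks
#'
#' Simulates one binary lesion mask per patient on the atlas grid.  Lesion
#' centres cluster around a small number of "territories" (standing in for
#' vascular territories): each territory has a centre voxel, and each
#' patient's lesion is grown from a seed displaced from a randomly chosen
#' territory centre by an isotropic Gaussian of SD `territory_spread`
#' voxels.  Every lesion is a single connected component with volume at
#' least `min_volume_mm3`, matching the inclusion rule applied to real
#' cohorts (focal lesions of at least 1 cm^3).
#'
#' @param atlas an [toy_atlas()] object supplying the grid.
#' @param n_patients number of masks to generate.
#' @param territory_params list with elements `territory_count` (default 2),
#'   `territory_spread` (SD of the seed displacement in voxels, default 3)
#'   and optionally `centres` (matrix of voxel coordinates, one row per
#'   territory; sampled from the central grid if absent).
#' @param seed integer seed.
#' @param volume_meanlog,volume_sdlog lognormal parameters (in voxels) for
#'   the target lesion size; defaults give a median around 16 cm^3 on a
#'   2 mm grid, typical of middle-cerebral-artery stroke.
#' @param min_volume_mm3 lower bound on lesion volume (default 1000 mm^3).
#'
#' @return List of `n_patients` binary arrays (0/1) of the atlas grid size.
#' @export
generate_lesion_masks <- function(atlas, n_patients,
                                  territory_params = list(), seed = 1L,
                                  volume_meanlog = log(2000),
                                  volume_sdlog = 0.6,
                                  min_volume_mm3 = 1000) {
  stopifnot(inherits(atlas, "ld_atlas"), n_patients >= 1L)
  dims <- atlas$grid_dims
  tp <- utils::modifyList(list(territory_count = 2L, territory_spread = 3),
                          territory_params)
  min_vox <- ceiling(min_volume_mm3 / atlas$voxel_volume)
  with_seed(seed, {
    centres <- tp$centres
    if (is.null(centres)) {
      centres <- cbind(
        round(runif(tp$territory_count, dims[1L] * 0.25, dims[1L] * 0.75)),
        round(runif(tp$territory_count, dims[2L] * 0.25, dims[2L] * 0.75)),
        round(runif(tp$territory_count, dims[3L] * 0.25, dims[3L] * 0.75))
      )
    }
    centres <- matrix(as.numeric(centres), ncol = 3L)
    if (any(centres < 1) || any(t(centres) > dims)) {
      stop("territory centre outside the grid", call. = FALSE)
    }
    lapply(seq_len(n_patients), function(i) {
      terr <- sample.int(nrow(centres), 1L)
      repeat {
        pos <- round(centres[terr, ] + rnorm(3L, 0, tp$territory_spread))
        if (all(pos >= 1) && all(pos <= dims)) break
      }
      start <- as.integer((pos[3L] - 1L) * dims[1L] * dims[2L] +
                            (pos[2L] - 1L) * dims[1L] + pos[1L])
      target <- max(min_vox, round(rlnorm(1L, volume_meanlog, volume_sdlog)))
      target <- min(target, prod(dims))
      vox <- grow_blob(dims, start, target)
      arr <- array(0L, dims)
      arr[vox] <- 1L
      arr
    })
  })
}

#' Write lesion masks as NIfTI-1 images
#'
#' @param masks list of binary arrays.
#' @param dir output directory.
#' @param ids patient identifiers used in filenames.
#' @param voxel_volume mm^3 per voxel, stored in the header pixel dims.
#' @return Character vector of file paths, invisibly.
#' @export
write_lesion_masks <- function(masks, dir, ids = seq_along(masks),
                               voxel_volume = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge <- voxel_volume^(1 / 3)
  paths <- file.path(dir, sprintf("lesion_%s.nii.gz", ids))
  for (i in seq_along(masks)) {
    img <- RNifti::asNifti(array(as.integer(masks[[i]]), dim(masks[[i]])))
    img <- RNifti::`pixdim<-`(img, rep(edge, 3))
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read binary lesion masks from NIfTI-1 images
#'
#' @param paths character vector of file paths.
#' @return List of binary integer arrays.
#' @export
read_lesion_masks <- function(paths) {
  lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    stop_if_not_binary(img, basename(p))
    array(as.integer(img), dim(img))
  })
}
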