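#' Toy brain atlas objects
#'
#' A toy atlas is a parcellation of a 3D voxel grid into named regions.
#' Regions are stored as sets of linear voxel indices and are allowed to
#' overlap, mirroring parcellations assembled from several anatomical
#' atlases at once.  Lesion loads are computed per region against such an
#' atlas, so nothing downstream assumes disjointness.
#'
#' @param grid_dims integer vector of length 3, grid size in voxels.
#' @param voxel_volume volume of one voxel in mm^3.
#' @param regions named list of integer vectors of linear voxel indices.
#' @param hemisphere_tag free-text tag for the hemisphere covered.
#'
#' @return An object of class `ld_atlas`.
#' @export
toy_atlas <- function(grid_dims, voxel_volume, regions, hemisphere_tag = "L") {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L),
            is.numeric(voxel_volume), voxel_volume > 0,
            is.list(regions), length(regions) >= 1L)
  nm <- names(regions)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("regions must have unique non-empty names", call. = FALSE)
  }
  nvox <- prod(grid_dims)
  for (r in nm) {
    v <- regions[[r]]
    if (length(v) == 0L) stop(sprintf("region '%s' is empty", r), call. = FALSE)
    if (any(v < 1L | v > nvox)) {
      stop(sprintf("region '%s' has voxel indices outside the grid", r),
           call. = FALSE)
    }
    regions[[r]] <- sort(unique(as.integer(v)))
  }
  structure(
    list(grid_dims = grid_dims, voxel_volume = voxel_volume,
         regions = regions, hemisphere_tag = hemisphere_tag),
    class = "ld_atlas"
  )
}

#' @export
print.ld_atlas <- function(x, ...) {
  cat(sprintf("<ld_atlas> %d regions on a %s grid (%.1f mm^3/voxel, %s)\n",
              length(x$regions), paste(x$grid_dims, collapse = "x"),
              x$voxel_volume, x$hemisphere_tag))
  invisible(x)
}

# 6-neighbour linear indices within the grid (face connectivity, used for
# blob growth so generated shapes stay compact).
neighbours6 <- function(idx, dims) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  i0 <- idx - 1L
  x <- i0 %% nx
  y <- (i0 %/% nx) %% ny
  z <- i0 %/% (nx * ny)
  out <- c(
    idx[x > 0L] - 1L, idx[x < nx - 1L] + 1L,
    idx[y > 0L] - nx, idx[y < ny - 1L] + nx,
    idx[z > 0L] - nx * ny, idx[z < nz - 1L] + nx * ny
  )
  unique(out)
}

# Grow a connected blob of ~target_size voxels from a start voxel by
# stochastic frontier accretion.  Always returns a 6-connected (hence also
# 26-connected) set containing `start`; size is exact unless the grid
# saturates first.
grow_blob <- function(dims, start, target_size, accept = 0.7, avoid = NULL) {
  nvox <- prod(dims)
  member <- logical(nvox)
  member[start] <- TRUE
  size <- 1L
  frontier <- setdiff(neighbours6(start, dims), start)
  if (!is.null(avoid)) frontier <- frontier[!avoid[frontier]]
  while (size < target_size && length(frontier) > 0L) {
    take <- frontier[runif(length(frontier)) < accept]
    if (length(take) == 0L) {
      take <- frontier[sample.int(length(frontier), 1L)]
    }
    if (length(take) > target_size - size) {
      take <- take[sample.int(length(take), target_size - size)]
    }
    member[take] <- TRUE
    size <- size + length(take)
    grown <- neighbours6(take, dims)
    frontier <- setdiff(unique(c(frontier, grown)), which(member))
    frontier <- frontier[!member[frontier]]
    if (!is.null(avoid)) frontier <- frontier[!avoid[frontier]]
  }
  which(member)
}

#' Generate a toy atlas
#'
#' Grows `n_regions` compact, possibly overlapping regions on a voxel grid.
#' A fraction `overlap_fraction` of region seeds is placed inside already
#' grown regions, which guarantees overlap between regions much as a union
#' of several anatomical parcellations overlaps.
#'
#' @param grid_dims grid size in voxels (length-3 integer).
#' @param n_regions number of regions to generate.
#' @param overlap_fraction fraction in \[0,1\] of regions seeded inside an
#'   existing region.
#' @param seed integer seed; the atlas is a deterministic function of all
#'   arguments.
#' @param voxel_volume mm^3 per voxel (default 8, i.e. 2 mm isotropic).
#' @param region_size_range inclusive range of region sizes in voxels.
#'
#' @return An [toy_atlas()] object with regions named `region_001`, ...
#' @export
generate_atlas <- function(grid_dims = c(24L, 28L, 24L), n_regions = 199L,
                           overlap_fraction = 0.25, seed = 1L,
                           voxel_volume = 8, region_size_range = c(30L, 120L)) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(n_regions >= 1L, overlap_fraction >= 0, overlap_fraction <= 1)
  nvox <- prod(grid_dims)
  if (nvox < n_regions * 8L) {
    stop(sprintf("grid of %d voxels too small to host %d regions",
                 nvox, n_regions), call. = FALSE)
  }
  with_seed(seed, {
    regions <- vector("list", n_regions)
    covered <- logical(nvox)
    sizes <- sample(region_size_range[1L]:region_size_range[2L], n_regions,
                    replace = TRUE)
    inside <- runif(n_regions) < overlap_fraction
    for (k in seq_len(n_regions)) {
      cov_idx <- which(covered)
      if (inside[k] && length(cov_idx) > 0L) {
        # overlapping region: seeded inside existing coverage, grows freely
        start <- cov_idx[sample.int(length(cov_idx), 1L)]
        regions[[k]] <- grow_blob(grid_dims, start, sizes[k])
      } else {
        # non-overlapping region: seeded and grown on uncovered voxels only
        free <- which(!covered)
        if (length(free) == 0L) {
          stop(sprintf("grid of %d voxels too small to host %d regions",
                       nvox, n_regions), call. = FALSE)
        }
        start <- free[sample.int(length(free), 1L)]
        regions[[k]] <- grow_blob(grid_dims, start, sizes[k],
                                  avoid = covered)
      }
      covered[regions[[k]]] <- TRUE
    }
    names(regions) <- sprintf("region_%03d", seq_len(n_regions))
    toy_atlas(grid_dims, voxel_volume, regions)
  })
}

#' Read a parcellation from disk
#'
#' Two on-disk forms are supported: a NIfTI-1 integer label image (one
#' region per non-zero label, named `region_<label>`), or a directory of
#' binary region-mask NIfTI images listed in a tab-separated manifest with
#' columns `name` and `file` (paths relative to the manifest).  Only the
#' directory form can represent overlapping regions.
#'
#' @param path path to a label image, or to a manifest TSV.
#' @param voxel_volume mm^3 per voxel; if `NULL`, taken from the image
#'   header (product of the first three pixel dimensions).
#' @return An `ld_atlas`.
#' @export
read_atlas <- function(path, voxel_volume = NULL) {
  if (grepl("\\.tsv$", path)) {
    manifest <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "file") %in% names(manifest)))
    dir <- dirname(path)
    regions <- list()
    dims <- NULL
    for (i in seq_len(nrow(manifest))) {
      img <- RNifti::readNifti(file.path(dir, manifest$file[i]))
      if (is.null(dims)) {
        dims <- dim(img)
        if (is.null(voxel_volume)) voxel_volume <- prod(RNifti::pixdim(img)[1:3])
      } else if (!identical(dim(img), dims)) {
        stop("region masks have inconsistent grids", call. = FALSE)
      }
      stop_if_not_binary(img, manifest$name[i])
      regions[[manifest$name[i]]] <- which(as.vector(img) == 1)
    }
    toy_atlas(dims, voxel_volume, regions)
  } else {
    img <- RNifti::readNifti(path)
    lab <- as.vector(img)
    if (is.null(voxel_volume)) voxel_volume <- prod(RNifti::pixdim(img)[1:3])
    labs <- sort(unique(lab[lab != 0]))
    regions <- lapply(labs, function(l) which(lab == l))
    names(regions) <- sprintf("region_%03d", as.integer(labs))
    toy_atlas(dim(img), voxel_volume, regions)
  }
}

#' Write an atlas as binary region masks plus a manifest
#'
#' @param atlas an `ld_atlas`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge <- atlas$voxel_volume^(1 / 3)
  files <- character(length(atlas$regions))
  for (i in seq_along(atlas$regions)) {
    arr <- array(0L, atlas$grid_dims)
    arr[atlas$regions[[i]]] <- 1L
    files[i] <- sprintf("%s.nii.gz", names(atlas$regions)[i])
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, rep(edge, 3))
    RNifti::writeNifti(img, file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "atlas_manifest.tsv")
  write.table(data.frame(name = names(atlas$regions), file = files),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
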