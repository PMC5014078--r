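#' Per-region lesion load
#'
#' Encodes a binary lesion mask as the percentage of each atlas region's
#' voxels that are lesioned: 0 when the region is untouched, 100 when it is
#' completely destroyed.  Regions may overlap; each is scored
#' independently.
#'
#' @param mask binary array on the atlas grid.
#' @param atlas an [toy_atlas()] object.
#' @return Named numeric vector of loads in \[0, 100\], one per region.
#' @export
lesion_load <- function(mask, atlas) {
  stopifnot(inherits(atlas, "ld_atlas"))
  if (!identical(as.integer(dim(mask)), atlas$grid_dims)) {
    stop("mask dimensions do not match the atlas grid", call. = FALSE)
  }
  stop_if_not_binary(mask)
  v <- as.vector(mask)
  vapply(atlas$regions, function(r) 100 * sum(v[r]) / length(r), numeric(1))
}

conn_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) {
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  } else if (connectivity == 18L) {
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= 2L, ]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  # keep one of each +/- pair; edges are undirected
  as.matrix(g[g$dx > 0 | (g$dx == 0 & g$dy > 0) |
                (g$dx == 0 & g$dy == 0 & g$dz > 0), ])
}

#' Volume of the largest connected lesion component
#'
#' Labels the connected components of a binary mask (26-connectivity by
#' default, the usual rule for lesion blobs) and returns the volume of the
#' largest one in mm^3.  Used to apply the focality inclusion rule: a
#' patient is retained only when some contiguous damaged volume reaches
#' 1 cm^3.
#'
#' @param mask binary 3D array.
#' @param voxel_volume mm^3 per voxel.
#' @param connectivity 6, 18 or 26 (voxels sharing a face, an edge, or any
#'   corner count as neighbours).
#' @return Volume in mm^3; 0 for an empty mask.
#' @export
largest_component_volume <- function(mask, voxel_volume = 8,
                                     connectivity = 26L) {
  stop_if_not_binary(mask)
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  vox <- which(as.vector(mask) == 1)
  if (length(vox) == 0L) return(0)
  pos <- arrayInd(vox, dims)
  id <- array(0L, dims)
  id[vox] <- seq_along(vox)
  offs <- conn_offsets(as.integer(connectivity))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    q <- pos + matrix(offs[k, ], nrow(pos), 3L, byrow = TRUE)
    ok <- q[, 1L] >= 1L & q[, 1L] <= dims[1L] &
      q[, 2L] >= 1L & q[, 2L] <= dims[2L] &
      q[, 3L] >= 1L & q[, 3L] <= dims[3L]
    nb <- id[q[ok, , drop = FALSE]]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(vox),
                          directed = FALSE)
  max(igraph::components(g)$csize) * voxel_volume
}

#' Apply automatable inclusion criteria
#'
#' Screens a raw cohort against the two rules that can be applied
#' mechanically: patients assessed less than 3 months post-stroke are
#' excluded (code `lt3months`), as are patients whose largest contiguous
#' lesion component is below 1 cm^3 (code `sub_cm3`).  When both rules
#' apply, the time rule is recorded (rules are checked in order).
#'
#' @param masks list of binary lesion arrays, one per patient.
#' @param time_post_stroke numeric vector, months since stroke at
#'   assessment.
#' @param voxel_volume mm^3 per voxel.
#' @param connectivity connectivity rule for contiguity (default 26).
#' @param min_months,min_volume_mm3 the two thresholds.
#' @return List with `retained` (integer indices) and `exclusions`
#'   (data.frame of `index`, `code`).
#' @export
apply_inclusion_criteria <- function(masks, time_post_stroke,
                                     voxel_volume = 8, connectivity = 26L,
                                     min_months = 3, min_volume_mm3 = 1000) {
  n <- length(masks)
  if (length(time_post_stroke) != n) {
    stop("one time_post_stroke value per mask is required", call. = FALSE)
  }
  if (any(vapply(masks, is.null, logical(1)))) {
    stop("every patient needs a lesion mask", call. = FALSE)
  }
  codes <- character(0); idx <- integer(0)
  retained <- logical(n)
  for (i in seq_len(n)) {
    if (time_post_stroke[i] < min_months) {
      idx <- c(idx, i); codes <- c(codes, "lt3months")
    } else if (largest_component_volume(masks[[i]], voxel_volume,
                                        connectivity) < min_volume_mm3) {
      idx <- c(idx, i); codes <- c(codes, "sub_cm3")
    } else {
      retained[i] <- TRUE
    }
  }
  list(retained = which(retained),
       exclusions = data.frame(index = idx, code = codes,
                               stringsAsFactors = FALSE))
}

#' Assemble the predictor table
#'
#' Builds the patients-by-predictors design table: one column of lesion
#' load per atlas region, followed by total lesion volume (mm^3), time
#' post-stroke (months), sex (0 = female, 1 = male) and age at stroke
#' (years).  With a 199-region parcellation this is the 203-predictor
#' encoding used for prognostic modelling.
#'
#' @param cohort an `ld_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @return data.frame with one row per patient; attribute
#'   `region_names` records which columns are regions.
#' @export
build_predictor_table <- function(cohort) {
  stopifnot(inherits(cohort, "ld_cohort"))
  regions <- names(cohort$atlas$regions)
  if (!identical(colnames(cohort$loads), regions)) {
    stop("cohort lesion loads do not match the atlas regions", call. = FALSE)
  }
  tab <- as.data.frame(cohort$loads)
  tab$lesion_volume <- cohort$lesion_volume
  tab$time_post_stroke <- cohort$demographics$time_post_stroke
  tab$sex <- cohort$demographics$sex
  tab$age <- cohort$demographics$age_at_stroke
  rownames(tab) <- cohort$demographics$id
  attr(tab, "region_names") <- regions
  tab
}
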