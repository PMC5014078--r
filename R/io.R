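#' Write a cohort to disk
#'
#' Persists a cohort as flat files: per-patient NIfTI-1 lesion masks (when
#' present), the atlas as binary region masks with a manifest, and
#' tab-separated tables for demographics, lesion loads, lesion volumes,
#' task scores, native-language scores and history fields.  The
#' simulation configuration and master seed are recorded in
#' `config.json` so a written cohort can be regenerated byte-for-byte.
#'
#' @param cohort an `ld_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ld_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas"))
  if (!is.null(cohort$masks)) {
    write_lesion_masks(cohort$masks, file.path(dir, "masks"),
                       ids = cohort$demographics$id,
                       voxel_volume = cohort$atlas$voxel_volume)
  }
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(cohort$demographics, "demographics.tsv")
  wt(data.frame(id = cohort$demographics$id, cohort$loads,
                check.names = FALSE), "lesion_loads.tsv")
  wt(data.frame(id = cohort$demographics$id,
                lesion_volume = cohort$lesion_volume), "lesion_volume.tsv")
  wt(data.frame(id = cohort$demographics$id, cohort$scores,
                check.names = FALSE), "scores.tsv")
  wt(data.frame(id = cohort$demographics$id, cohort$native_scores,
                check.names = FALSE), "native_scores.tsv")
  wt(cohort$history, "history.tsv")
  cfg <- cohort$config
  cfg$true_weights <- NULL  # regenerated from the seed
  jsonlite::write_json(
    list(config = unclass(cfg), seed = cohort$seed,
         scale = unclass(cohort$scale)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory written by [write_cohort()].
#' @return An `ld_cohort` (without masks; lesion loads are read from the
#'   stored table).
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas", "atlas_manifest.tsv"))
  rd <- function(f) read.delim(file.path(dir, f), check.names = FALSE,
                               stringsAsFactors = FALSE)
  demog <- rd("demographics.tsv")
  mat <- function(f) {
    d <- rd(f)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$id
    m
  }
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- do.call(simulation_config,
                    meta$config[names(meta$config) %in%
                                  names(formals(simulation_config))])
  scale <- structure(meta$scale, class = "ld_scale")
  structure(list(atlas = atlas, demographics = demog,
                 loads = mat("lesion_loads.tsv"),
                 lesion_volume = rd("lesion_volume.tsv")$lesion_volume,
                 scores = mat("scores.tsv"),
                 native_scores = mat("native_scores.tsv"),
                 history = rd("history.tsv"),
                 scale = scale, config = config, seed = meta$seed),
            class = "ld_cohort")
}
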