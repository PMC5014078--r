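#' Region frequency map
#'
#' Counts, for each atlas region, the number of tasks in which the region
#' appears — either in the selected best models (pass a list of
#' `ld_model`s) or in the shared strong lesion-deficit associations
#' (pass the `strong_b` table of an `ld_screen`, where only `shared`
#' rows are counted).
#'
#' @param x named list of `ld_model` objects, or a data.frame with
#'   columns `region`, `task` and optionally `shared`.
#' @param regions character vector of valid region names.
#' @return Named integer vector (one count per `regions` entry).
#' @export
region_frequency <- function(x, regions) {
  counts <- stats::setNames(integer(length(regions)), regions)
  if (is.data.frame(x)) {
    if (nrow(x) > 0 && "shared" %in% names(x)) x <- x[x$shared, ]
    hit <- unique(x[, c("region", "task")])
    if (nrow(hit) > 0 && !all(hit$region %in% regions)) {
      stop("unknown region label in association table", call. = FALSE)
    }
    tab <- table(hit$region)
    counts[names(tab)] <- as.integer(tab)
  } else {
    if (length(x) == 0L) stop("empty model list", call. = FALSE)
    for (m in x) {
      fs <- if (inherits(m, "ld_model")) m$features else m
      hit <- intersect(fs, regions)
      counts[hit] <- counts[hit] + 1L
    }
  }
  counts
}

#' Export a region frequency map
#'
#' Writes the counts as a TSV and, optionally, paints them onto the atlas
#' as a NIfTI image (each voxel takes the maximum count over the regions
#' containing it, since regions may overlap).
#'
#' @param counts named counts from [region_frequency()].
#' @param atlas the `ld_atlas` the counts refer to.
#' @param tsv_path,nifti_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_region_frequency <- function(counts, atlas, tsv_path = NULL,
                                   nifti_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(data.frame(region = names(counts),
                           count = as.integer(counts)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(nifti_path)) {
    arr <- array(0L, atlas$grid_dims)
    ord <- order(counts)  # paint ascending so maxima win
    for (i in ord) {
      v <- atlas$regions[[names(counts)[i]]]
      arr[v] <- pmax(arr[v], counts[i])
    }
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, rep(atlas$voxel_volume^(1 / 3), 3))
    RNifti::writeNifti(img, nifti_path)
  }
  invisible(c(tsv_path, nifti_path))
}

#' Run the full lesion-deficit transfer pipeline
#'
#' Orchestrates the end-to-end analysis on a cohort: per-task feature
#' selection on group a, transfer prediction for group b, per-task
#' prediction-error shift tests with a permutation family-wise threshold,
#' the random-model consistency ensemble over the flagged tasks, the
#' Bayes-factor convergence screen with the paired slope comparison, the
#' language-history screen, and region frequency maps.  Every stage is a
#' deterministic function of the cohort and the seeds; when `out_dir` is
#' given, each stage's artefacts are written as flat TSV/JSON files as
#' soon as the stage finishes, together with a manifest sufficient to
#' reproduce the run.
#'
#' @param cohort an `ld_cohort` (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param tasks tasks to analyse (default: all).
#' @param criterion selection criterion, `"mae"` or `"rmse"`.
#' @param n_perm permutations for the family-wise threshold; `0` skips
#'   permutation thresholding and flags tasks at the uncorrected level
#'   (marked `"uncorrected"` in the result).
#' @param n_random_models size of the random-model ensemble; `0` skips
#'   the ensemble.
#' @param random_size_range feature-set size range for the ensemble.
#' @param seed master seed for the permutation and ensemble draws.
#' @param alpha nominal family-wise level.
#' @param out_dir optional output directory for stage artefacts.
#' @return List of class `ld_run` with elements `models`, `records`,
#'   `shift`, `null`, `flagged_tasks`, `ensemble`, `screen`, `slopes`,
#'   `history`, `freq_models`, `freq_shared`, `manifest`.
#' @export
run_pipeline <- function(cohort, tasks = colnames(cohort$scores),
                         criterion = "mae", n_perm = 1000L,
                         n_random_models = 1000L,
                         random_size_range = c(2L, 40L),
                         seed = 1L, alpha = 0.05, out_dir = NULL) {
  stopifnot(inherits(cohort, "ld_cohort"))
  persist <- function(name, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(file.path(out_dir, name))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tab <- build_predictor_table(cohort)
  is_a <- cohort$demographics$group == "a"
  table_a <- tab[is_a, , drop = FALSE]
  table_b <- tab[!is_a, , drop = FALSE]
  scores_a <- cohort$scores[is_a, , drop = FALSE]
  scores_b <- cohort$scores[!is_a, , drop = FALSE]

  models <- stage("select", {
    ms <- lapply(tasks, function(task) {
      select_features(table_a, scores_a[, task], criterion = criterion,
                      task = task, group = "a")
    })
    stats::setNames(ms, tasks)
  })
  persist("models.json", function(p) write_models(models, p))

  records <- stage("transfer",
                   transfer_predict(models, table_a, scores_a,
                                    table_b, scores_b))
  persist("prediction_records.tsv", function(p)
    write.table(records, p, sep = "\t", quote = FALSE, row.names = FALSE))

  shift <- stage("shift_tests", shift_tests(records))
  null <- NULL
  if (n_perm > 0L) {
    null <- stage("permutation",
                  permutation_familywise_threshold(
                    records, n_perm = n_perm,
                    seed = derive_seed(seed, 21L), alpha = alpha))
    shift$threshold <- null$corrected_alpha
    shift$correction <- "permutation"
  } else {
    shift$threshold <- alpha
    shift$correction <- "uncorrected"
  }
  shift$significant <- !is.na(shift$p) & shift$p <= shift$threshold
  persist("shift_tests.tsv", function(p)
    write.table(shift, p, sep = "\t", quote = FALSE, row.names = FALSE))
  flagged <- shift$task[shift$significant & shift$t > 0]

  ensemble <- NULL
  if (n_random_models > 0L && length(flagged) > 0L) {
    ensemble <- stage("ensemble", {
      sets <- sample_random_feature_sets(
        n_random_models,
        c(random_size_range[1L],
          min(random_size_range[2L], ncol(tab))),
        labels = colnames(tab), seed = derive_seed(seed, 22L))
      random_model_consistency(sets, table_a, scores_a, table_b, scores_b,
                               flagged, shift$threshold)
    })
    persist("ensemble.json", function(p)
      jsonlite::write_json(ensemble, p, auto_unbox = TRUE, digits = NA))
  }

  screen <- NULL; slopes <- NULL
  if (length(flagged) > 0L) {
    screen <- stage("associations",
                    convergence_screen(cohort, tasks = flagged))
    persist("associations.tsv", function(p)
      write_screen(screen, tsv_path = p,
                   json_path = file.path(out_dir, "divergent.json")))
    if (sum(screen$strong_b$shared) >= 2L) {
      slopes <- stage("slopes", slope_comparison(screen))
      persist("slope_comparison.json", function(p)
        jsonlite::write_json(slopes, p, auto_unbox = TRUE, digits = NA))
    }
  }

  history <- NULL
  if (length(flagged) > 0L && !all(is.na(cohort$history[-1L]))) {
    history <- stage("history", history_screen(cohort$history, records,
                                               flagged))
    persist("history_screen.tsv", function(p)
      write.table(history$table, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
  }

  regions <- names(cohort$atlas$regions)
  freq_models <- region_frequency(models, regions)
  freq_shared <- if (!is.null(screen)) {
    region_frequency(screen$strong_b, regions)
  } else NULL
  persist("region_frequency_models.tsv", function(p)
    write_region_frequency(freq_models, cohort$atlas, tsv_path = p))
  if (!is.null(freq_shared)) {
    persist("region_frequency_shared.tsv", function(p)
      write_region_frequency(freq_shared, cohort$atlas, tsv_path = p))
  }

  manifest <- list(
    config = unclass(cohort$config[setdiff(names(cohort$config),
                                           "true_weights")]),
    cohort_seed = cohort$seed, pipeline_seed = seed,
    tasks = tasks, criterion = criterion, n_perm = n_perm,
    n_random_models = n_random_models,
    random_size_range = random_size_range, alpha = alpha,
    r_version = as.character(getRversion()))
  persist("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))

  structure(list(models = models, records = records, shift = shift,
                 null = null, flagged_tasks = flagged,
                 ensemble = ensemble, screen = screen, slopes = slopes,
                 history = history, freq_models = freq_models,
                 freq_shared = freq_shared, manifest = manifest),
            class = "ld_run")
}

#' @export
print.ld_run <- function(x, ...) {
  cat(sprintf(
    "<ld_run> %d tasks, %d flagged (threshold %.4f, %s)\n",
    nrow(x$shift), length(x$flagged_tasks),
    x$shift$threshold[1L], x$shift$correction[1L]))
  if (!is.null(x$ensemble)) {
    cat(sprintf("  ensemble consistency: %.1f%% (%d/%d), %d opposite\n",
                100 * x$ensemble$fraction, x$ensemble$n_significant,
                x$ensemble$n_tests, x$ensemble$opposite_count))
  }
  if (!is.null(x$screen)) {
    cat(sprintf("  convergence screen: %d strong in group b, %d shared\n",
                x$screen$n_strong_b, x$screen$n_shared))
  }
  if (!is.null(x$slopes) && !x$slopes$degenerate) {
    cat(sprintf("  slope comparison: t = %.2f (df = %d, p = %.3g)\n",
                x$slopes$t, x$slopes$df, x$slopes$p))
  }
  invisible(x)
}
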