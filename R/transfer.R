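#' Cross-group transfer predictions
#'
#' Generates prediction records for both groups under the transfer
#' design: group a (the model-building group) is predicted by
#' leave-one-out cross-validation, while group b is predicted in a single
#' pass by a model trained on all of group a.  Each task uses its
#' complete cases.  Errors follow the convention `predicted - actual`:
#' positive error means the model overestimates the patient's ability.
#'
#' @param models named list (by task) of `ld_model` objects or plain
#'   character feature sets.
#' @param table_a,table_b predictor tables with identical headers.
#' @param scores_a,scores_b score matrices (patients x tasks), `NA`
#'   allowed.
#' @return data.frame with columns `id`, `task`, `group`, `predicted`,
#'   `actual`, `error`.
#' @export
transfer_predict <- function(models, table_a, scores_a, table_b, scores_b) {
  if (!identical(colnames(table_a), colnames(table_b))) {
    stop("predictor table headers differ between groups", call. = FALSE)
  }
  tasks <- names(models)
  stopifnot(!is.null(tasks), all(tasks %in% colnames(scores_a)))
  out <- vector("list", length(tasks))
  for (k in seq_along(tasks)) {
    task <- tasks[k]
    fs <- models[[k]]
    if (inherits(fs, "ld_model")) fs <- fs$features
    ya <- scores_a[, task]; yb <- scores_b[, task]
    ca <- which(!is.na(ya)); cb <- which(!is.na(yb))
    # drop features constant within the training cases (unusable there)
    Xa <- table_a[ca, fs, drop = FALSE]
    fs_use <- fs[vapply(fs, function(f) var(Xa[[f]]) > 0, logical(1))]
    if (length(fs_use) == 0L) fs_use <- fs[1L]
    pred_a <- loocv_predictions(fs_use, table_a[ca, , drop = FALSE], ya[ca])
    fit <- fit_linear_model(as.matrix(table_a[ca, fs_use, drop = FALSE]),
                            ya[ca])
    pred_b <- predict_linear(fit, table_b[cb, fs_use, drop = FALSE])
    out[[k]] <- data.frame(
      id = c(rownames(table_a)[ca], rownames(table_b)[cb]),
      task = task,
      group = rep(c("a", "b"), c(length(ca), length(cb))),
      predicted = c(pred_a, pred_b),
      actual = c(ya[ca], yb[cb]),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, out)
  records$error <- records$predicted - records$actual
  rownames(records) <- NULL
  records
}

#' Per-task prediction-error shift tests
#'
#' For each task, tests whether group b's prediction errors are shifted
#' relative to group a's with an independent-samples t-test (numerator
#' `mean(b) - mean(a)`, so positive t means group b's errors are
#' positively shifted, i.e. the model overestimates group b).  Variances
#' are pooled after a Levene pre-check; when the pre-check rejects at
#' `levene_alpha`, Welch's form is used instead.
#'
#' @param records prediction records from [transfer_predict()].
#' @param levene_gate run the Levene pre-check (default `TRUE`).
#' @param levene_alpha pre-check level (default 0.05).
#' @return data.frame with one row per task: `task`, `t`, `p`,
#'   `mean_error_a`, `mean_error_b`, `n_a`, `n_b`, `levene_p`,
#'   `equal_var`.
#' @export
shift_tests <- function(records, levene_gate = TRUE, levene_alpha = 0.05) {
  tasks <- unique(records$task)
  rows <- lapply(tasks, function(task) {
    ea <- records$error[records$task == task & records$group == "a"]
    eb <- records$error[records$task == task & records$group == "b"]
    lev_p <- NA_real_
    eq <- TRUE
    if (levene_gate) {
      lev <- levene_test(ea, eb)
      lev_p <- lev$p
      eq <- lev$p > levene_alpha
    }
    tt <- independent_t(eb, ea, equal_var = eq)
    data.frame(task = task, t = tt$t, p = tt$p,
               mean_error_a = mean(ea), mean_error_b = mean(eb),
               n_a = length(ea), n_b = length(eb),
               levene_p = lev_p, equal_var = eq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Vectorised pooled-variance t-tests of (group b - group a) for one error
# vector against many label permutations.  `is_b` is an n x B logical
# matrix of permuted group-b indicators.
perm_t_block <- function(e, is_b) {
  n <- length(e)
  nb <- colSums(is_b)
  na_ <- n - nb
  sb <- drop(crossprod(e, is_b))
  qb <- drop(crossprod(e^2, is_b))
  stot <- sum(e); qtot <- sum(e^2)
  mb <- sb / nb
  ma <- (stot - sb) / na_
  ssw <- (qb - nb * mb^2) + (qtot - qb - na_ * ma^2)
  sp2 <- ssw / (n - 2)
  t <- (mb - ma) / sqrt(sp2 * (1 / na_ + 1 / nb))
  t[nb < 2 | na_ < 2 | sp2 <= 0] <- NA_real_
  p <- 2 * pt(-abs(t), n - 2)
  list(t = t, p = p)
}

#' Permutation-based family-wise corrected threshold
#'
#' Builds the null distribution of the per-task shift tests by shuffling
#' the group labels of the pooled patients and recomputing every task's t
#' statistic, `n_perm` times.  One global label permutation is drawn per
#' iteration and applied within each task's complete cases, preserving
#' the between-task correlation of the statistics.  The corrected
#' per-test alpha is the largest threshold at which the fraction of
#' permutations whose *minimum* per-task p-value falls below it stays at
#' or below `alpha` (min-p / max-statistic family-wise control).
#'
#' @param records prediction records from [transfer_predict()].
#' @param n_perm number of permutations (default 1000; values below 100
#'   trigger a warning).
#' @param seed integer seed; the null is reproducible.
#' @param alpha nominal family-wise level (default 0.05).
#' @return List of class `ld_permnull`: `n_perm`, `min_p` (one per
#'   permutation), `corrected_alpha`, `alpha`, `seed`.
#' @export
permutation_familywise_threshold <- function(records, n_perm = 1000L,
                                             seed = 1L, alpha = 0.05) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null",
                             call. = FALSE)
  ids <- unique(records$id)
  grp <- records$group[match(ids, records$id)]
  n <- length(ids)
  if (sum(grp == "a") < 2L || sum(grp == "b") < 2L) {
    stop("need at least 2 patients per group", call. = FALSE)
  }
  tasks <- unique(records$task)
  with_seed(seed, {
    perm_idx <- vapply(seq_len(n_perm), function(j) sample.int(n),
                       integer(n))
    gp <- matrix(grp[perm_idx] == "b", n, n_perm)
    min_p <- rep(Inf, n_perm)
    for (task in tasks) {
      sel <- records$task == task
      rows <- match(records$id[sel], ids)
      e <- records$error[sel]
      res <- perm_t_block(e, gp[rows, , drop = FALSE])
      min_p <- pmin(min_p, res$p, na.rm = TRUE)
    }
    min_p[!is.finite(min_p)] <- NA_real_
    k <- max(1L, floor(alpha * n_perm))
    corrected <- sort(min_p)[k]
    corrected <- min(corrected, alpha)
    structure(list(n_perm = n_perm, min_p = min_p,
                   corrected_alpha = corrected, alpha = alpha, seed = seed),
              class = "ld_permnull")
  })
}

#' @export
print.ld_permnull <- function(x, ...) {
  cat(sprintf("<ld_permnull> %d permutations, corrected alpha = %.4f\n",
              x$n_perm, x$corrected_alpha))
  invisible(x)
}

#' Random-model consistency ensemble
#'
#' Re-runs the transfer analysis for an ensemble of random feature sets
#' and reports the fraction of (model, task) tests, over the tasks of
#' interest, that show a significant *positive* prediction-error shift at
#' the supplied (corrected) threshold — i.e. how typical the best models'
#' group distinction is of the model space at large.  Significant shifts
#' in the opposite direction are counted separately.
#'
#' @param random_sets list of feature sets from
#'   [sample_random_feature_sets()].
#' @param table_a,table_b,scores_a,scores_b as in [transfer_predict()].
#' @param tasks_of_interest tasks to evaluate (e.g. the tasks the best
#'   models flagged).
#' @param corrected_alpha per-test significance threshold.
#' @return List with `fraction`, `n_significant`, `n_tests`,
#'   `opposite_count` and a `per_task` data.frame.
#' @export
random_model_consistency <- function(random_sets, table_a, scores_a,
                                     table_b, scores_b, tasks_of_interest,
                                     corrected_alpha = 0.05) {
  stopifnot(length(random_sets) >= 1L)
  hits <- opp <- total <- stats::setNames(
    integer(length(tasks_of_interest)), tasks_of_interest)
  for (fs in random_sets) {
    models <- stats::setNames(rep(list(fs), length(tasks_of_interest)),
                              tasks_of_interest)
    rec <- suppressWarnings(
      transfer_predict(models, table_a, scores_a, table_b, scores_b))
    st <- shift_tests(rec, levene_gate = FALSE)
    sig <- !is.na(st$p) & st$p <= corrected_alpha
    hits <- hits + as.integer(sig & st$t > 0)[match(tasks_of_interest,
                                                    st$task)]
    opp <- opp + as.integer(sig & st$t < 0)[match(tasks_of_interest,
                                                  st$task)]
    total <- total + 1L
  }
  n_tests <- length(random_sets) * length(tasks_of_interest)
  list(fraction = sum(hits) / n_tests,
       n_significant = sum(hits), n_tests = n_tests,
       opposite_count = sum(opp),
       per_task = data.frame(task = tasks_of_interest,
                             n_significant = as.integer(hits),
                             n_models = length(random_sets),
                             stringsAsFactors = FALSE))
}

#' Screen language-history variables against prediction errors
#'
#' Correlates each history field with the prediction errors of the
#' transfer group, per flagged task, using pairwise-complete data.  Cells
#' with fewer than `min_n` complete pairs are skipped and logged.  The
#' p-values are nominal (unadjusted); a multiple-comparison note is
#' attached as an attribute of the returned table.
#'
#' @param history data.frame with an `id` column plus history fields.
#' @param records prediction records from [transfer_predict()].
#' @param flagged_tasks tasks to screen.
#' @param min_n minimum complete pairs per cell (default 3).
#' @return List with `table` (field, task, n, r, p) and `skipped`.
#' @export
history_screen <- function(history, records, flagged_tasks, min_n = 3L) {
  fields <- setdiff(colnames(history), "id")
  rows <- list(); skipped <- list()
  for (field in fields) {
    if (all(is.na(history[[field]]))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(field = field, task = NA_character_,
                   reason = "all_missing", stringsAsFactors = FALSE)
      next
    }
    for (task in flagged_tasks) {
      rec <- records[records$task == task & records$group == "b", ]
      h <- history[[field]][match(rec$id, history$id)]
      ok <- !is.na(h) & !is.na(rec$error)
      if (sum(ok) < min_n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(field = field, task = task,
                     reason = "insufficient_pairs", stringsAsFactors = FALSE)
        next
      }
      if (var(h[ok]) == 0 || var(rec$error[ok]) == 0) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(field = field, task = task,
                     reason = "constant", stringsAsFactors = FALSE)
        next
      }
      ct <- cor.test(h[ok], rec$error[ok], method = "pearson")
      rows[[length(rows) + 1L]] <-
        data.frame(field = field, task = task, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = character(0), task = character(0),
               n = integer(0), r = numeric(0), p = numeric(0))
  attr(tab, "note") <- paste(
    "p-values are nominal; with", nrow(tab),
    "tests, about", round(0.05 * nrow(tab), 1),
    "positives are expected by chance at alpha = 0.05")
  list(table = tab,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(field = character(0), task = character(0),
                    reason = character(0)))
}
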