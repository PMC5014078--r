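#' Region-wise lesion-load/score association table
#'
#' For every (region, task, group) cell, computes the complete-case
#' sample size, the Pearson correlation between lesion load and score,
#' the univariate regression slope (T-score units per % load), the
#' default correlation Bayes factor and its evidence category.  Cells
#' where the load or the score is constant within the group's complete
#' cases (e.g. a region no patient's lesion touches) carry `NA`
#' statistics with an `undefined` category; they cannot show evidence
#' either way.
#'
#' @param cohort an `ld_cohort`.
#' @param tasks tasks to include (default: all).
#' @param regions regions to include (default: all atlas regions).
#' @param min_n minimum complete cases for a computed Bayes factor.
#' @return data.frame with columns `region`, `task`, `group`, `n`, `r`,
#'   `slope`, `bf10`, `category`.
#' @export
region_associations <- function(cohort, tasks = colnames(cohort$scores),
                                regions = colnames(cohort$loads),
                                min_n = 3L) {
  stopifnot(inherits(cohort, "ld_cohort"))
  grp <- cohort$demographics$group
  out <- vector("list", length(tasks) * length(regions) * 2L)
  k <- 0L
  for (g in c("a", "b")) {
    gi <- which(grp == g)
    loads_g <- cohort$loads[gi, , drop = FALSE]
    scores_g <- cohort$scores[gi, , drop = FALSE]
    for (task in tasks) {
      y <- scores_g[, task]
      for (region in regions) {
        x <- loads_g[, region]
        ok <- !is.na(y)
        n <- sum(ok)
        k <- k + 1L
        if (n < min_n || var(x[ok]) == 0 || var(y[ok]) == 0) {
          out[[k]] <- data.frame(region = region, task = task, group = g,
                                 n = n, r = NA_real_, slope = NA_real_,
                                 bf10 = NA_real_, category = "undefined",
                                 stringsAsFactors = FALSE)
          next
        }
        r <- cor(x[ok], y[ok])
        slope <- r * sd(y[ok]) / sd(x[ok])
        bf <- default_bf_correlation(r, n)
        out[[k]] <- data.frame(region = region, task = task, group = g,
                               n = n, r = r, slope = slope, bf10 = bf,
                               category = classify_evidence(bf),
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Neural convergence screen
#'
#' Enumerates the (region, task) cells with strong evidence for a
#' lesion-load/score correlation in group b (BF10 > 10), and checks
#' whether the same association is also strong in group a.  Shared cases
#' support a common lesion-deficit architecture (convergence); cases
#' strong in b but not in a are returned as the divergent list, with
#' group a's Bayes factor attached so near-misses can be distinguished
#' from genuine absences.
#'
#' @param cohort an `ld_cohort`, or a precomputed association table from
#'   [region_associations()].
#' @param tasks,regions scope of the screen (defaults: all).
#' @return List of class `ld_screen`: `associations` (the full table),
#'   `strong_b` (cells strong in group b, with both groups' BF10),
#'   `n_strong_b`, `n_shared`, `divergent` (data.frame).
#' @export
convergence_screen <- function(cohort, tasks = NULL, regions = NULL) {
  assoc <- if (is.data.frame(cohort)) cohort else {
    region_associations(cohort,
                        tasks = tasks %||% colnames(cohort$scores),
                        regions = regions %||% colnames(cohort$loads))
  }
  a <- assoc[assoc$group == "a", ]
  b <- assoc[assoc$group == "b", ]
  key <- function(d) paste(d$region, d$task, sep = "\r")
  ia <- match(key(b), key(a))
  strong_b <- b[!is.na(b$bf10) & b$bf10 > 10, c("region", "task", "n",
                                                "r", "slope", "bf10")]
  names(strong_b)[3:6] <- paste0(names(strong_b)[3:6], "_b")
  ma <- a[ia[!is.na(b$bf10) & b$bf10 > 10], ]
  strong_b$n_a <- ma$n
  strong_b$r_a <- ma$r
  strong_b$slope_a <- ma$slope
  strong_b$bf10_a <- ma$bf10
  strong_b$shared <- !is.na(strong_b$bf10_a) & strong_b$bf10_a > 10
  rownames(strong_b) <- NULL
  structure(list(associations = assoc, strong_b = strong_b,
                 n_strong_b = nrow(strong_b),
                 n_shared = sum(strong_b$shared),
                 divergent = strong_b[!strong_b$shared, , drop = FALSE]),
            class = "ld_screen")
}

#' @export
print.ld_screen <- function(x, ...) {
  cat(sprintf("<ld_screen> %d strong group-b associations, %d shared, %d divergent\n",
              x$n_strong_b, x$n_shared, nrow(x$divergent)))
  invisible(x)
}

#' Paired comparison of lesion-deficit slopes across groups
#'
#' For the shared strong (region, task) cases, compares the two groups'
#' univariate slopes of score on lesion load with a paired-samples
#' t-test.  The statistic is computed on `slope_a - slope_b`, so a
#' positive t means group b's slopes are systematically more negative —
#' greater deficit per unit of damage in the same regions.  When the
#' slope pairs are identical the t statistic is undefined and a
#' degenerate result (`NA` statistics, `degenerate = TRUE`) is returned.
#'
#' @param screen an `ld_screen` from [convergence_screen()], or a
#'   data.frame with columns `slope_a` and `slope_b`.
#' @param shared_only restrict to the shared strong cases (default
#'   `TRUE`, applies when `screen` is an `ld_screen`).
#' @return List with `t`, `p`, `df`, `mean_diff` (mean of
#'   `slope_a - slope_b`), `n`, `degenerate`.
#' @export
slope_comparison <- function(screen, shared_only = TRUE) {
  cases <- if (inherits(screen, "ld_screen")) {
    if (shared_only) screen$strong_b[screen$strong_b$shared, ] else
      screen$strong_b
  } else {
    screen
  }
  if (nrow(cases) < 2L) stop("need at least 2 shared cases", call. = FALSE)
  d <- cases$slope_a - cases$slope_b
  if (sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), n = nrow(cases), degenerate = TRUE))
  }
  tt <- paired_t(d)
  list(t = tt$t, p = tt$p, df = tt$df, mean_diff = tt$mean_diff,
       n = nrow(cases), degenerate = FALSE)
}

#' Write an association table as TSV / a divergent list as JSON
#'
#' @param screen an `ld_screen`.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_screen <- function(screen, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(screen, "ld_screen"))
  if (!is.null(tsv_path)) {
    write.table(screen$associations, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_strong_b = screen$n_strong_b, n_shared = screen$n_shared,
           divergent = screen$divergent,
           note = "no multiplicity correction inside the screen; evidence categories follow Jeffreys thresholds"),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
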