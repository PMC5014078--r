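#' Least-squares linear model fit
#'
#' Ordinary least squares with an intercept.  When the design (including
#' the intercept column) is rank deficient, the minimum-norm least-squares
#' solution is returned (Moore-Penrose pseudoinverse), so duplicated
#' predictors share their weight equally and the fit is always defined.
#'
#' @param X numeric matrix of predictors (no intercept column).
#' @param y numeric response vector.
#' @return List with `intercept` and `coefficients` (one per column of
#'   `X`).
#' @export
fit_linear_model <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 1L || nrow(X) != n) stop("empty or mismatched data", call. = FALSE)
  A <- cbind(`(Intercept)` = 1, X)
  qa <- qr(A)
  beta <- if (qa$rank == ncol(A)) {
    qr.coef(qa, y)
  } else {
    s <- svd(A)
    pos <- s$d > max(s$d) * max(dim(A)) * .Machine$double.eps
    drop(s$v[, pos, drop = FALSE] %*%
           ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos]))
  }
  list(intercept = unname(beta[1L]),
       coefficients = stats::setNames(beta[-1L], colnames(X)))
}

predict_linear <- function(fit, X) {
  drop(as.matrix(X) %*% fit$coefficients) + fit$intercept
}

#' Leave-one-out cross-validated predictions
#'
#' For each patient, predicts their score from a model trained on all
#' other patients.  When the full design is of full column rank the exact
#' closed-form LOOCV residual `e_i / (1 - h_ii)` is used (identical to
#' refitting n times, but a single fit); otherwise, and for any
#' leverage-one rows, per-fold refits with the minimum-norm solution are
#' used and a degenerate-fold warning is raised.
#'
#' @param feature_set character vector of column names of `table`.
#' @param table predictor data.frame/matrix.
#' @param y response vector (no missing values; subset to complete cases
#'   first).
#' @return Numeric vector of LOOCV predictions, one per row.
#' @export
loocv_predictions <- function(feature_set, table, y) {
  X <- as.matrix(table[, feature_set, drop = FALSE])
  n <- length(y)
  stopifnot(nrow(X) == n)
  A <- cbind(1, X)
  qa <- qr(A)
  full_rank <- qa$rank == ncol(A) && n > ncol(A)
  if (full_rank) {
    Q <- qr.Q(qa)
    h <- rowSums(Q^2)
    res <- y - qr.fitted(qa, y)
    ok <- h < 1 - 1e-10
    pred <- y - res / (1 - h)
    if (all(ok)) return(pred)
    redo <- which(!ok)
  } else {
    warning("degenerate fold(s): design not full rank for n-1 rows; ",
            "minimum-norm fits used", call. = FALSE)
    pred <- numeric(n)
    redo <- seq_len(n)
  }
  for (i in redo) {
    fit <- fit_linear_model(X[-i, , drop = FALSE], y[-i])
    pred[i] <- predict_linear(fit, X[i, , drop = FALSE])
  }
  pred
}

#' Prediction-error criterion
#'
#' Mean absolute error by default (the criterion the per-task prediction
#' tables report); root-mean-square error available as an alternative.
#'
#' @param predictions,y equal-length numeric vectors.
#' @param type `"mae"` or `"rmse"`.
#' @return Non-negative scalar.
#' @export
selection_criterion <- function(predictions, y, type = c("mae", "rmse")) {
  type <- match.arg(type)
  if (length(y) == 0L || length(predictions) != length(y)) {
    stop("predictions and y must be non-empty and of equal length",
         call. = FALSE)
  }
  e <- predictions - y
  if (type == "mae") mean(abs(e)) else sqrt(mean(e^2))
}

#' Iterated forward-selection / backwards-elimination feature search
#'
#' Starting from the seed feature set (time post-stroke by default), the
#' forward phase repeatedly adds the candidate whose addition most reduces
#' the leave-one-out cross-validation error, until no addition improves
#' it; the backward phase repeatedly removes the member whose removal most
#' reduces the error, until no removal improves it.  The two-phase cycle
#' repeats until a full cycle changes nothing.  A step is accepted only if
#' it improves the criterion by more than `tol` (preventing cycling on
#' ties); candidate ties are broken by the lowest column index.  The seed
#' feature is not protected from elimination.  Zero-variance candidates
#' within the current data subset are skipped.
#'
#' @param table predictor data.frame (complete rows for this task).
#' @param y response vector, same length as `nrow(table)`; rows with
#'   missing `y` are dropped (complete-case analysis per task).
#' @param seed_features initial feature set.
#' @param candidates columns eligible for selection (default: all columns
#'   of `table`).
#' @param criterion `"mae"` (default) or `"rmse"`.
#' @param tol minimum criterion improvement for a step to be accepted.
#' @param task,group optional labels stored in the result.
#' @return A `ld_model`: list with `features`, `intercept`,
#'   `coefficients`, `criterion`, `trace` (data.frame of accepted steps),
#'   `n`, `task`, `group`.
#' @export
select_features <- function(table, y, seed_features = "time_post_stroke",
                            candidates = colnames(table),
                            criterion = "mae", tol = 1e-9,
                            task = NA_character_, group = NA_character_) {
  keep <- !is.na(y)
  if (!any(keep)) stop("all responses missing", call. = FALSE)
  table <- table[keep, , drop = FALSE]
  y <- y[keep]
  stopifnot(all(seed_features %in% colnames(table)))
  candidates <- intersect(candidates, colnames(table))
  usable <- candidates[vapply(candidates,
                              function(f) var(table[[f]]) > 0, logical(1))]
  eval_crit <- function(fs) {
    selection_criterion(loocv_predictions(fs, table, y), y, criterion)
  }
  current <- seed_features
  crit <- eval_crit(current)
  trace <- data.frame(step = 0L, action = "seed",
                      feature = paste(seed_features, collapse = "+"),
                      criterion = crit, stringsAsFactors = FALSE)
  step <- 0L
  col_rank <- stats::setNames(seq_along(colnames(table)), colnames(table))
  repeat {
    changed <- FALSE
    # forward phase
    repeat {
      pool <- setdiff(usable, current)
      if (length(pool) == 0L) break
      vals <- vapply(pool, function(f) eval_crit(c(current, f)), numeric(1))
      best <- which(vals == min(vals))
      best <- best[which.min(col_rank[pool[best]])]
      if (crit - vals[best] > tol) {
        current <- c(current, pool[best])
        crit <- vals[best]
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "add",
                                         feature = pool[best],
                                         criterion = crit))
        changed <- TRUE
      } else break
    }
    # backward phase
    repeat {
      if (length(current) <= 1L) break
      vals <- vapply(seq_along(current),
                     function(i) eval_crit(current[-i]), numeric(1))
      best <- which(vals == min(vals))
      best <- best[which.min(col_rank[current[best]])]
      if (crit - vals[best] > tol) {
        removed <- current[best]
        current <- current[-best]
        crit <- vals[best]
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         feature = removed,
                                         criterion = crit))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- fit_linear_model(table[, current, drop = FALSE], y)
  structure(list(features = current, intercept = fit$intercept,
                 coefficients = fit$coefficients, criterion = crit,
                 criterion_type = criterion, trace = trace,
                 n = length(y), task = task, group = group),
            class = "ld_model")
}

#' @export
print.ld_model <- function(x, ...) {
  cat(sprintf("<ld_model> %s: %d features, LOOCV %s = %.3f (n = %d)\n",
              x$task %||% "?", length(x$features), x$criterion_type,
              x$criterion, x$n))
  invisible(x)
}

#' Sample random feature sets
#'
#' Draws feature sets for the robustness ensemble: set sizes are uniform
#' over `size_range` and members are drawn uniformly without replacement
#' from `labels`.  Default size range 2-40 spans the sizes selected
#' feature searches typically produce, with margin.
#'
#' @param n_models number of sets.
#' @param size_range inclusive integer range of set sizes.
#' @param labels pool of feature labels.
#' @param seed integer seed; output is reproducible.
#' @return List of character vectors.
#' @export
sample_random_feature_sets <- function(n_models, size_range = c(2L, 40L),
                                       labels, seed = 1L) {
  size_range <- as.integer(size_range)
  if (size_range[1L] < 1L || size_range[2L] > length(labels) ||
      size_range[1L] > size_range[2L]) {
    stop("invalid size range", call. = FALSE)
  }
  with_seed(seed, {
    sizes <- sample(size_range[1L]:size_range[2L], n_models, replace = TRUE)
    lapply(sizes, function(k) labels[sample.int(length(labels), k)])
  })
}

#' Serialize prognostic models to JSON
#'
#' @param models list of `ld_model` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  jsonlite::write_json(
    lapply(models, function(m) {
      list(task = m$task, group = m$group, features = m$features,
           intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           criterion = m$criterion, criterion_type = m$criterion_type,
           n = m$n, trace = m$trace)
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
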