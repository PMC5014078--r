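#' Simulation configuration for synthetic two-group cohorts
#'
#' Collects every knob of the synthetic-cohort generator.  The defaults
#' encode the study conditions the pipeline is designed around: a large
#' reference group (`n_group_a`, monolingual analogue, default 174) and a
#' small transfer group (`n_group_b`, bilingual analogue, default 33), a
#' 199-region overlapping parcellation, 22 task scores generated linearly
#' from lesion loads plus time post-stroke with Gaussian noise, and two
#' separately controllable group differences:
#'
#' * `lambda_sensitivity` multiplies the (negative) lesion-load
#'   coefficients for group b — "enhanced sensitivity to damage";
#' * `intercept_shift` adds a constant (in T-score units) to group b's
#'   expected scores — a premorbid-proficiency-style main effect.
#'
#' @param n_group_a,n_group_b patient counts for the two groups.
#' @param n_regions,n_tasks atlas regions and task scores to simulate.
#' @param true_weights optional list with elements `intercept`,
#'   `load` (n_tasks x n_regions matrix, T-score units per % load),
#'   `time`, `age`, `sex` (length-n_tasks vectors) and optionally
#'   `load_b`, a group-b-specific load-weight matrix for simulating
#'   divergent lesion-deficit architectures.  When `NULL`,
#'   weights are drawn once, deterministically from `seed`: each task gets
#'   `n_active_regions` regions with loads drawn from `weight_range`
#'   (negative — damage lowers scores) and a small positive time
#'   coefficient (slow recovery with time post-stroke).
#' @param lambda_sensitivity multiplier (>= 0) on group-b lesion-load
#'   coefficients; 1 means no sensitivity difference.
#' @param intercept_shift additive shift (T-score units) on group-b
#'   expected scores; 0 means none.
#' @param noise_sd residual SD in T-score units.
#' @param missing_rate per-entry MCAR missingness probability for task
#'   scores.
#' @param territory_count,territory_spread lesion-geometry controls passed
#'   to [generate_lesion_masks()].
#' @param n_active_regions regions with non-zero weight per task.
#' @param weight_range magnitude range for lesion-load weights (T per %).
#' @param time_weight coefficient on time post-stroke (T per month).
#' @param history_effect if non-zero, injects an association of this
#'   correlation strength between one language-history field and the
#'   lesion-driven deficit (for power-testing the history screen);
#'   default 0 (history independent of outcomes, the null).
#' @param seed master integer seed; every random draw in the generator is
#'   derived from it.
#'
#' @return A list of class `ld_simconfig`.
#' @export
simulation_config <- function(n_group_a = 174L, n_group_b = 33L,
                              n_regions = 199L, n_tasks = 22L,
                              true_weights = NULL,
                              lambda_sensitivity = 1,
                              intercept_shift = 0,
                              noise_sd = 5,
                              missing_rate = 0.03,
                              territory_count = 2L, territory_spread = 5,
                              n_active_regions = 5L,
                              weight_range = c(0.04, 0.12),
                              time_weight = 0.02,
                              history_effect = 0,
                              seed = 1L) {
  stopifnot(n_group_a >= 1L, n_group_b >= 1L, n_regions >= 1L, n_tasks >= 1L,
            lambda_sensitivity >= 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "ld_simconfig")
}

# Resolve the per-task generative weights, drawing them deterministically
# from the config seed when not supplied.  Lesion-load weights are
# negative: damage lowers scores.
resolve_weights <- function(config) {
  if (!is.null(config$true_weights)) return(config$true_weights)
  with_seed(derive_seed(config$seed, 2L), {
    load_w <- matrix(0, config$n_tasks, config$n_regions)
    k <- min(config$n_active_regions, config$n_regions)
    for (t in seq_len(config$n_tasks)) {
      active <- sample.int(config$n_regions, k)
      load_w[t, active] <- -runif(k, config$weight_range[1L],
                                  config$weight_range[2L])
    }
    list(intercept = rep(60, config$n_tasks),
         load = load_w,
         time = rep(config$time_weight, config$n_tasks),
         age = rep(0, config$n_tasks),
         sex = rep(0, config$n_tasks))
  })
}

#' Score standardization scale
#'
#' Task scores are reported as T-scores referenced to a simulated sample
#' of 60 aphasic patients: T = 50 + 10 (x - mean) / SD, computed per task.
#' An impairment cutoff is taken at the 5th percentile of a simulated
#' sample of 27 neurologically normal controls, converted to the same T
#' scale: performance below it would put a patient in the bottom 5% of the
#' normal population.
#'
#' @param reference_raw 60 x n_tasks matrix of raw reference scores.
#' @param control_raw 27 x n_tasks matrix of raw control scores.
#' @return List of class `ld_scale` with per-task `reference_mean`,
#'   `reference_sd` and `impairment_cutoff` (on the T scale).
#' @export
score_scale <- function(reference_raw, control_raw) {
  m <- colMeans(reference_raw)
  s <- apply(reference_raw, 2L, sd)
  if (any(s <= 0)) stop("reference scores are constant for some task",
                        call. = FALSE)
  cutoff_raw <- apply(control_raw, 2L, quantile, probs = 0.05, names = FALSE)
  structure(list(reference_mean = m, reference_sd = s,
                 impairment_cutoff = 50 + 10 * (cutoff_raw - m) / s),
            class = "ld_scale")
}

#' Convert raw scores to T-scores
#'
#' @param raw matrix (or vector) of raw scores, tasks in columns.
#' @param scale an [score_scale()] object.
#' @return T-scores (mean 50, SD 10 in the reference sample).
#' @export
t_score <- function(raw, scale) {
  raw <- as.matrix(raw)
  sweep(sweep(raw, 2L, scale$reference_mean), 2L,
        scale$reference_sd / 10, "/") + 50
}

#' Generate task scores from lesion loads and demographics
#'
#' Expected raw score for patient i on task t is
#' `intercept_t + sum_r w_tr load_ir + w_time time_i (+ age, sex terms)`,
#' with group-b lesion-load weights multiplied by `lambda_sensitivity` and
#' group-b expected scores shifted by `intercept_shift`.  Gaussian noise
#' with SD `noise_sd` is added, scores are converted to T-scores when a
#' scale is supplied (shift and noise are specified in T units and mapped
#' onto the raw scale through the reference SD), and entries are deleted
#' independently at `missing_rate` (missing completely at random).
#'
#' @param lesion_loads n x n_regions matrix of loads in \[0,100\].
#' @param demographics data.frame with columns `group` ("a"/"b"),
#'   `time_post_stroke`, `age_at_stroke`, `sex`.
#' @param config an [simulation_config()].
#' @param scale an [score_scale()], or `NULL` to return raw scores
#'   (then shift/noise are applied in raw units and no entries are
#'   deleted).
#' @param seed seed for noise and missingness (default derived from the
#'   config seed).
#' @return n x n_tasks matrix of scores (T-scores when `scale` given),
#'   `NA` for missing entries.
#' @export
generate_scores <- function(lesion_loads, demographics, config, scale = NULL,
                            seed = derive_seed(config$seed, 3L)) {
  w <- resolve_weights(config)
  lesion_loads <- as.matrix(lesion_loads)
  if (ncol(lesion_loads) != ncol(w$load)) {
    stop("lesion_loads columns do not match the weight support",
         call. = FALSE)
  }
  if (nrow(lesion_loads) != nrow(demographics)) {
    stop("lesion_loads rows do not match demographics", call. = FALSE)
  }
  n <- nrow(lesion_loads)
  is_b <- demographics$group == "b"
  # per-task raw-unit equivalents of the T-unit shift and noise
  unit <- if (is.null(scale)) rep(1, config$n_tasks) else scale$reference_sd / 10
  expected <- matrix(w$intercept, n, config$n_tasks, byrow = TRUE) +
    lesion_loads %*% t(w$load) +
    outer(demographics$time_post_stroke, w$time) +
    outer(demographics$age_at_stroke, w$age) +
    outer(demographics$sex, w$sex)
  if (any(is_b)) {
    # group b may have its own lesion-load weight matrix (`load_b`, for
    # simulating divergent architectures); lambda scales whichever applies
    wb <- (w$load_b %||% w$load) * config$lambda_sensitivity
    lb <- lesion_loads[is_b, , drop = FALSE]
    expected[is_b, ] <- expected[is_b, ] - lb %*% t(w$load) + lb %*% t(wb) +
      matrix(config$intercept_shift * unit, sum(is_b), config$n_tasks,
             byrow = TRUE)
  }
  with_seed(seed, {
    raw <- expected + matrix(rnorm(n * config$n_tasks), n) *
      matrix(config$noise_sd * unit, n, config$n_tasks, byrow = TRUE)
    out <- if (is.null(scale)) raw else {
      tt <- t_score(raw, scale)
      tt[matrix(runif(length(tt)) < config$missing_rate, n)] <- NA
      tt
    }
    colnames(out) <- sprintf("task_%02d", seq_len(config$n_tasks))
    rownames(out) <- demographics$id
    out
  })
}

sim_demographics <- function(n, group, seed) {
  p_male <- if (group == "a") 112 / 174 else 18 / 33
  mu_age <- if (group == "a") 53.0 else 49.0
  sd_age <- if (group == "a") 12.2 else 13.2
  with_seed(seed, {
    age <- pmin(pmax(rnorm(n, mu_age, sd_age), 18), 90)
    tps <- rlnorm(n, 3.61, 0.9)
    while (any(tps < 3)) tps[tps < 3] <- rlnorm(sum(tps < 3), 3.61, 0.9)
    data.frame(id = sprintf("%s_%03d", group, seq_len(n)),
               group = group,
               sex = rbinom(n, 1L, p_male),
               age_at_stroke = age,
               time_post_stroke = tps,
               stringsAsFactors = FALSE)
  })
}

sim_history <- function(demographics, deficit, config, seed) {
  n <- nrow(demographics)
  is_b <- demographics$group == "b"
  nb <- sum(is_b)
  # response rates per field follow a typical language-history
  # questionnaire (many patients leave questions unanswered)
  resp <- c(n_languages = 30, age_of_bilingualism = 26, age_learned_l2 = 24,
            years_l2_used = 24, premorbid_proficiency = 26,
            pct_use_pre = 15, pct_use_post = 27) / 33
  with_seed(seed, {
    h <- data.frame(
      n_languages = pmax(2, round(rlnorm(n, log(3.2), 0.35))),
      age_of_bilingualism = round(pmin(pmax(rnorm(n, 5.5, 3), 0), 10)),
      age_learned_l2 = round(pmin(pmax(rlnorm(n, log(10), 0.6), 2), 42)),
      years_l2_used = round(pmin(pmax(rnorm(n, 40, 15), 5), 80)),
      premorbid_proficiency = round(pmin(pmax(rnorm(n, 8.1, 0.9), 1), 9), 1),
      pct_use_pre = round(pmin(pmax(rnorm(n, 74, 18), 0), 100)),
      pct_use_post = round(pmin(pmax(rnorm(n, 65, 22), 0), 100))
    )
    if (config$history_effect != 0 && nb > 1L) {
      # inject a correlation between years of use and lesion-driven deficit
      z <- scale(deficit[is_b])[, 1L]
      rho <- config$history_effect
      mix <- rho * z + sqrt(1 - rho^2) * rnorm(nb)
      h$years_l2_used[is_b] <- round(40 + 15 * mix)
    }
    for (f in names(resp)) {
      h[[f]][runif(n) > resp[[f]]] <- NA
    }
    h[!is_b, ] <- NA
    cbind(demographics["id"], h)
  })
}

#' Generate a complete synthetic two-group cohort
#'
#' Runs the full generator: toy atlas, territory-structured lesions for
#' both patient groups, a 60-patient aphasic reference sample and
#' 27-control sample defining the T-score scale, task scores with the
#' configured group differences, native-language scores for 7 of the
#' tasks in group b, and language-history fields with realistic
#' per-question response rates.  Everything is a deterministic function of
#' the configuration (including its seed).
#'
#' @param config an [simulation_config()].
#' @param atlas optionally, a pre-built [toy_atlas()]; generated from the
#'   config otherwise.
#' @param keep_masks keep the binary masks in the returned object
#'   (needed by [write_cohort()]).
#' @return A list of class `ld_cohort` with elements `atlas`,
#'   `demographics`, `loads`, `lesion_volume`, `scores`,
#'   `native_scores`, `history`, `scale`, `config` and (optionally)
#'   `masks`.
#' @export
generate_cohort <- function(config = simulation_config(), atlas = NULL,
                            keep_masks = FALSE) {
  stopifnot(inherits(config, "ld_simconfig"))
  seed <- config$seed
  if (is.null(atlas)) {
    atlas <- generate_atlas(n_regions = config$n_regions,
                            seed = derive_seed(seed, 1L))
  }
  tp <- list(territory_count = config$territory_count,
             territory_spread = config$territory_spread)
  n_a <- config$n_group_a; n_b <- config$n_group_b
  masks <- generate_lesion_masks(atlas, n_a + n_b, tp,
                                 seed = derive_seed(seed, 4L))
  ref_masks <- generate_lesion_masks(atlas, 60L, tp,
                                     seed = derive_seed(seed, 5L))
  demog <- rbind(sim_demographics(n_a, "a", derive_seed(seed, 6L)),
                 sim_demographics(n_b, "b", derive_seed(seed, 7L)))
  ref_demog <- sim_demographics(60L, "a", derive_seed(seed, 8L))
  ref_demog$group <- "a"

  loads <- t(vapply(masks, lesion_load, numeric(length(atlas$regions)),
                    atlas = atlas))
  rownames(loads) <- demog$id
  ref_loads <- t(vapply(ref_masks, lesion_load,
                        numeric(length(atlas$regions)), atlas = atlas))
  lesion_volume <- vapply(masks, function(m) sum(m) * atlas$voxel_volume,
                          numeric(1))

  # reference sample (aphasic) and controls (no lesion) define the scale
  ref_raw <- generate_scores(ref_loads, ref_demog, config, scale = NULL,
                             seed = derive_seed(seed, 9L))
  ctl_demog <- sim_demographics(27L, "a", derive_seed(seed, 10L))
  ctl_demog$time_post_stroke <- 0
  ctl_raw <- generate_scores(matrix(0, 27L, config$n_regions), ctl_demog,
                             config, scale = NULL,
                             seed = derive_seed(seed, 11L))
  scale <- score_scale(ref_raw, ctl_raw)

  scores <- generate_scores(loads, demog, config, scale = scale,
                            seed = derive_seed(seed, 12L))

  # native-language (L1) scores for 7 tasks, group b only; L1 scores run a
  # few T-units below the (dominant-exposure) L2 scores
  n_native <- min(7L, config$n_tasks)
  native <- matrix(NA_real_, n_a + n_b, n_native,
                   dimnames = list(demog$id,
                                   colnames(scores)[seq_len(n_native)]))
  is_b <- demog$group == "b"
  with_seed(derive_seed(seed, 13L), {
    for (j in seq_len(n_native)) {
      have <- is_b & runif(n_a + n_b) < 0.6 & !is.na(scores[, j])
      native[have, j] <- scores[have, j] + rnorm(sum(have), -3, 4)
    }
  })

  deficit <- (loads %*% t(resolve_weights(config)$load))[, 1L]
  history <- sim_history(demog, deficit, config, derive_seed(seed, 14L))

  out <- list(atlas = atlas, demographics = demog, loads = loads,
              lesion_volume = lesion_volume, scores = scores,
              native_scores = native, history = history,
              scale = scale, config = config, seed = seed)
  if (keep_masks) out$masks <- masks
  structure(out, class = "ld_cohort")
}

#' Build a cohort from an explicit lesion-load matrix
#'
#' Constructs a cohort directly from per-region lesion loads, bypassing
#' the mask geometry.  Useful for simulations that need a prescribed
#' load covariance structure (e.g. independent loads across regions when
#' studying parameter recovery of the region-wise slope analysis).
#'
#' @param loads n x n_regions matrix of loads in \[0,100\], with region
#'   column names.
#' @param demographics data.frame with `id`, `group`, `sex`,
#'   `age_at_stroke`, `time_post_stroke`.
#' @param config an [simulation_config()]; scores are generated from it.
#' @param scale optional [score_scale()]; raw scores returned when
#'   `NULL`.
#' @return An `ld_cohort` (without atlas or masks).
#' @export
cohort_from_loads <- function(loads, demographics, config, scale = NULL) {
  scores <- generate_scores(loads, demographics, config, scale = scale)
  structure(list(atlas = NULL, demographics = demographics,
                 loads = loads,
                 lesion_volume = rep(NA_real_, nrow(loads)),
                 scores = scores, native_scores = NULL, history = NULL,
                 scale = scale, config = config, seed = config$seed),
            class = "ld_cohort")
}

#' Per-group univariate slopes at the generatively active cells
#'
#' For every (task, region) cell with a non-zero lesion-load weight in
#' the cohort's generating configuration, computes each group's
#' univariate regression slope of score on lesion load.  The ratio
#' `slope_b / slope_a` estimates the group-b sensitivity multiplier
#' (lambda): a parameter-recovery diagnostic for the region-wise slope
#' analysis.
#'
#' @param cohort an `ld_cohort` generated by this package.
#' @param min_load_sd cells whose load SD (either group) falls below
#'   this are dropped as unidentifiable.
#' @return data.frame with `task`, `region`, `slope_a`, `slope_b`,
#'   `ratio`.
#' @export
active_slope_table <- function(cohort, min_load_sd = 1) {
  w <- resolve_weights(cohort$config)
  grp <- cohort$demographics$group
  rows <- list()
  for (t in seq_len(ncol(cohort$scores))) {
    for (r in which(w$load[t, ] != 0)) {
      x <- cohort$loads[, r]
      y <- cohort$scores[, t]
      oa <- grp == "a" & !is.na(y)
      ob <- grp == "b" & !is.na(y)
      if (sd(x[oa]) < min_load_sd || sd(x[ob]) < min_load_sd) next
      rows[[length(rows) + 1L]] <- data.frame(
        task = colnames(cohort$scores)[t],
        region = colnames(cohort$loads)[r],
        slope_a = cov(x[oa], y[oa]) / var(x[oa]),
        slope_b = cov(x[ob], y[ob]) / var(x[ob]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$ratio <- tab$slope_b / tab$slope_a
  tab
}

#' @export
print.ld_cohort <- function(x, ...) {
  cat(sprintf(
    "<ld_cohort> %d + %d patients, %d regions, %d tasks (lambda=%g, delta=%g)\n",
    sum(x$demographics$group == "a"), sum(x$demographics$group == "b"),
    ncol(x$loads), ncol(x$scores),
    x$config$lambda_sensitivity, x$config$intercept_shift))
  invisible(x)
}
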