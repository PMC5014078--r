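make_demog <- function(n, group = "a") {
  data.frame(id = sprintf("%s%02d", group, seq_len(n)), group = group,
             sex = rep_len(c(0, 1), n),
             age_at_stroke = seq(40, 60, length.out = n),
             time_post_stroke = seq(4, 60, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("noiseless scores are an exact affine function of predictors", {
  cfg <- simulation_config(n_group_a = 30L, n_group_b = 1L,
                           n_regions = 6L, n_tasks = 3L, noise_sd = 0,
                           missing_rate = 0, seed = 5L)
  set.seed(1)
  loads <- matrix(runif(30 * 6, 0, 80), 30)
  demog <- make_demog(30)
  raw <- generate_scores(loads, demog, cfg, scale = NULL)
  w <- lesionprog:::resolve_weights(cfg)
  for (t in 1:3) {
    fit <- lm(raw[, t] ~ loads + demog$time_post_stroke)
    expect_equal(unname(coef(fit)[2:7]), w$load[t, ], tolerance = 1e-8)
    expect_equal(unname(coef(fit)[8]), w$time[t], tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), w$intercept[t], tolerance = 1e-8)
  }
})

test_that("T-scoring the reference sample gives mean 50 and SD 10", {
  set.seed(2)
  ref <- matrix(rnorm(60 * 4, 55, 9), 60)
  ctl <- matrix(rnorm(27 * 4, 70, 5), 27)
  scale <- score_scale(ref, ctl)
  tt <- t_score(ref, scale)
  expect_equal(unname(colMeans(tt)), rep(50, 4), tolerance = 1e-9)
  expect_equal(unname(apply(tt, 2, sd)), rep(10, 4), tolerance = 1e-9)
  # impairment cutoff sits at the controls' 5th percentile on the T scale
  ctl_t <- t_score(ctl, scale)
  expect_equal(unname(scale$impairment_cutoff),
               unname(apply(ctl_t, 2, quantile, 0.05)), tolerance = 1e-9)
})

test_that("higher sensitivity strictly lowers group-b expected scores", {
  cfg <- simulation_config(n_group_a = 1L, n_group_b = 1L, n_regions = 4L,
                           n_tasks = 2L, noise_sd = 0,
                           lambda_sensitivity = 1.5, seed = 3L)
  loads <- rbind(rep(40, 4), rep(40, 4))
  demog <- make_demog(2)
  demog$group <- c("a", "b")
  demog$time_post_stroke <- c(12, 12)
  demog$age_at_stroke <- c(50, 50)
  demog$sex <- c(1, 1)
  raw <- generate_scores(loads, demog, cfg, scale = NULL)
  expect_true(all(raw[2, ] < raw[1, ]))
})

test_that("missingness hits the configured MCAR rate", {
  cfg <- simulation_config(n_group_a = 100L, n_group_b = 1L,
                           n_regions = 2L, n_tasks = 10L,
                           missing_rate = 0.2, seed = 8L)
  loads <- matrix(runif(100 * 2, 0, 50), 100)
  demog <- make_demog(100)
  ref <- matrix(rnorm(60 * 10, 60, 6), 60)
  ctl <- matrix(rnorm(27 * 10, 70, 4), 27)
  sc <- generate_scores(loads, demog, cfg, scale = score_scale(ref, ctl))
  frac <- mean(is.na(sc))
  expect_gte(frac, 0.17)  # binomial 99% interval at n = 1000
  expect_lte(frac, 0.23)
})

test_that("group labels are exchangeable when lambda = 1 and delta = 0", {
  cfg <- simulation_config(n_group_a = 20L, n_group_b = 20L,
                           n_regions = 4L, n_tasks = 1L, noise_sd = 5,
                           missing_rate = 0, seed = 4L)
  set.seed(9)
  loads <- matrix(runif(40 * 4, 0, 60), 40)
  loads[21:40, ] <- loads[1:20, ]  # matched lesion loads across groups
  demog <- make_demog(40)
  demog$group <- rep(c("a", "b"), each = 20)
  demog$time_post_stroke <- rep(demog$time_post_stroke[1:20], 2)
  demog$age_at_stroke <- rep(demog$age_at_stroke[1:20], 2)
  demog$sex <- rep(demog$sex[1:20], 2)
  hits <- 0L
  for (rep_i in 1:200) {
    raw <- generate_scores(loads, demog, cfg, scale = NULL, seed = rep_i)
    p <- t.test(raw[demog$group == "b", 1], raw[demog$group == "a", 1],
                var.equal = TRUE)$p.value
    hits <- hits + (p > 0.05)
  }
  expect_gte(hits / 200, 0.90)  # nominal 95%, binomial slack
})

test_that("cohorts have the configured sizes and are reproducible", {
  cfg <- simulation_config(n_group_a = 10L, n_group_b = 5L,
                           n_regions = 5L, n_tasks = 2L, seed = 6L)
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$demographics), 15L)
  expect_identical(table(co$demographics$group)[["a"]], 10L)
  co2 <- generate_cohort(cfg)
  expect_identical(co$scores, co2$scores)
  expect_identical(co$loads, co2$loads)
  expect_identical(co$history, co2$history)
  # default study sizes: 174 + 33
  cfg_def <- simulation_config(n_regions = 4L, n_tasks = 1L, seed = 2L)
  co_def <- generate_cohort(cfg_def)
  expect_identical(sum(co_def$demographics$group == "a"), 174L)
  expect_identical(sum(co_def$demographics$group == "b"), 33L)
})

test_that("native scores and history exist only for group b", {
  co <- shared_cohort()
  is_a <- co$demographics$group == "a"
  expect_true(all(is.na(co$native_scores[is_a, ])))
  expect_true(any(!is.na(co$native_scores[!is_a, ])))
  hist_fields <- setdiff(colnames(co$history), "id")
  expect_true(all(is.na(co$history[is_a, hist_fields])))
  expect_true(any(!is.na(co$history[!is_a, hist_fields])))
})

test_that("cohorts round-trip through the on-disk format", {
  cfg <- simulation_config(n_group_a = 6L, n_group_b = 4L, n_regions = 4L,
                           n_tasks = 2L, seed = 12L)
  co <- generate_cohort(cfg, keep_masks = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$loads, co$loads, tolerance = 1e-9)
  expect_equal(back$scores, co$scores, tolerance = 1e-9)
  expect_identical(back$demographics$id, co$demographics$id)
  expect_equal(back$config$seed, co$config$seed)
})
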