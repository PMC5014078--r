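test_that("the association table reports n, r, slope, BF and category", {
  co <- shared_cohort()
  assoc <- region_associations(co, tasks = "task_01")
  expect_identical(sort(unique(assoc$group)), c("a", "b"))
  expect_identical(nrow(assoc), 2L * ncol(co$loads))
  ok <- !is.na(assoc$r)
  expect_true(all(abs(assoc$r[ok]) <= 1))
  expect_true(all(assoc$bf10[ok] > 0))
  expect_true(all(assoc$n[ok] >= 3))
  # slope equals r * sd(y) / sd(x) for a spot-checked cell
  row <- assoc[ok, ][1, ]
  gi <- co$demographics$group == row$group
  y <- co$scores[gi, row$task]
  x <- co$loads[gi, row$region]
  cc <- !is.na(y)
  expect_equal(row$slope,
               unname(coef(lm(y[cc] ~ x[cc]))[2]), tolerance = 1e-10)
  expect_equal(row$r, cor(x[cc], y[cc]), tolerance = 1e-12)
})

test_that("pure-noise scores produce an empty strong set", {
  cfg <- simulation_config(n_group_a = 40L, n_group_b = 12L,
                           n_regions = 6L, n_tasks = 2L,
                           noise_sd = 5, seed = 19L,
                           true_weights = list(
                             intercept = rep(60, 2),
                             load = matrix(0, 2, 6),
                             time = rep(0, 2), age = rep(0, 2),
                             sex = rep(0, 2)))
  co <- generate_cohort(cfg)
  screen <- convergence_screen(co)
  expect_identical(screen$n_strong_b, 0L)
  expect_identical(screen$n_shared, 0L)
  expect_identical(nrow(screen$divergent), 0L)
})

test_that("a divergent region is flagged by the convergence screen", {
  # one region drives group-b scores only; loads are made independent
  # across regions so the univariate screen can isolate the signal
  n_regions <- 6L
  n_a <- 174L; n_b <- 33L
  w0 <- matrix(0, 1, n_regions)
  wa <- w0; wa[1, 1] <- -0.1            # group a depends on region 1
  wb <- w0; wb[1, 1] <- -0.1; wb[1, 4] <- -0.12  # b also on region 4
  cfg <- simulation_config(n_group_a = n_a, n_group_b = n_b,
                           n_regions = n_regions, n_tasks = 1L,
                           noise_sd = 1.5, missing_rate = 0, seed = 29L,
                           true_weights = list(
                             intercept = 60, load = wa, load_b = wb,
                             time = 0, age = 0, sex = 0))
  set.seed(31)
  loads <- matrix(runif((n_a + n_b) * n_regions, 0, 80), n_a + n_b,
                  dimnames = list(NULL, sprintf("region_%03d",
                                                seq_len(n_regions))))
  demog <- data.frame(id = sprintf("p%03d", seq_len(n_a + n_b)),
                      group = rep(c("a", "b"), c(n_a, n_b)),
                      sex = 0, age_at_stroke = 50,
                      time_post_stroke = 12)
  scores <- generate_scores(loads, demog, cfg, scale = NULL)
  co <- structure(list(loads = loads, scores = scores,
                       demographics = demog), class = "ld_cohort")
  screen <- convergence_screen(co)
  expect_true("region_004" %in% screen$divergent$region)
  # the shared architecture (region 1) is strong in both groups
  shared <- screen$strong_b[screen$strong_b$shared, ]
  expect_true("region_001" %in% shared$region)
  expect_false("region_004" %in% shared$region)
})

test_that("slope comparison detects enhanced group-b sensitivity", {
  cfg <- simulation_config(n_group_a = 174L, n_group_b = 33L,
                           n_regions = 8L, n_tasks = 2L,
                           n_active_regions = 8L,
                           noise_sd = 2, missing_rate = 0,
                           lambda_sensitivity = 1.5, seed = 37L)
  co <- generate_cohort(cfg)
  screen <- convergence_screen(co)
  expect_gte(screen$n_shared, 2L)
  res <- slope_comparison(screen)
  expect_false(res$degenerate)
  expect_gt(res$t, 0)  # group-b slopes more negative
  expect_lt(res$p, 0.05)
  expect_identical(res$df, res$n - 1L)
})

test_that("identical slope pairs give an explicit degenerate result", {
  cases <- data.frame(slope_a = c(-1, -2, -3), slope_b = c(-1, -2, -3))
  res <- slope_comparison(cases)
  expect_true(res$degenerate)
  expect_true(is.na(res$t))
  expect_error(slope_comparison(cases[1, , drop = FALSE]), "2 shared")
})

test_that("screens serialize to TSV and JSON", {
  co <- shared_cohort()
  screen <- convergence_screen(co, tasks = "task_01")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "assoc.tsv")
  js <- file.path(dir, "div.json")
  write_screen(screen, tsv, js)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(screen$associations))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(meta$n_strong_b, screen$n_strong_b)
})
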