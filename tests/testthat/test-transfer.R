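make_transfer_fixture <- function(lambda = 1, delta = 0, n_tasks = 2L,
                                  seed = 42L) {
  cfg <- simulation_config(n_group_a = 60L, n_group_b = 15L,
                           n_regions = 10L, n_tasks = n_tasks,
                           lambda_sensitivity = lambda,
                           intercept_shift = delta, seed = seed)
  co <- generate_cohort(cfg)
  tab <- build_predictor_table(co)
  is_a <- co$demographics$group == "a"
  list(cohort = co,
       table_a = tab[is_a, , drop = FALSE],
       table_b = tab[!is_a, , drop = FALSE],
       scores_a = co$scores[is_a, , drop = FALSE],
       scores_b = co$scores[!is_a, , drop = FALSE])
}

test_that("transfer predictions are complete-case and order-invariant", {
  fx <- make_transfer_fixture()
  models <- list(task_01 = c("region_001", "time_post_stroke"),
                 task_02 = c("region_002", "time_post_stroke"))
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  expect_identical(sort(unique(rec$task)), c("task_01", "task_02"))
  expect_equal(rec$error, rec$predicted - rec$actual)
  # permuting group-b patients leaves their records unchanged
  perm <- rev(seq_len(nrow(fx$table_b)))
  rec2 <- transfer_predict(models, fx$table_a, fx$scores_a,
                           fx$table_b[perm, ], fx$scores_b[perm, ])
  b1 <- rec[rec$group == "b", ]
  b2 <- rec2[rec2$group == "b", ]
  b2 <- b2[match(paste(b1$id, b1$task), paste(b2$id, b2$task)), ]
  expect_equal(b1$predicted, b2$predicted, tolerance = 1e-10)
  expect_error(
    transfer_predict(models, fx$table_a[, -1], fx$scores_a,
                     fx$table_b, fx$scores_b),
    "headers differ")
})

test_that("a negative group-b intercept shift yields positive errors", {
  # the model, trained on group a, overestimates group b when group b's
  # expected scores are shifted down
  fx <- make_transfer_fixture(lambda = 1, delta = -8, seed = 11L)
  models <- list(task_01 = c(colnames(fx$cohort$loads), "time_post_stroke"))
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  st <- shift_tests(rec)
  expect_gt(st$mean_error_b[1], 0)
  expect_gt(st$t[1], 0)
})

test_that("shift tests gate the pooled t on a Levene pre-check", {
  fx <- make_transfer_fixture(seed = 13L)
  models <- list(task_01 = c("region_001", "time_post_stroke"))
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  st <- shift_tests(rec)
  ea <- rec$error[rec$group == "a"]
  eb <- rec$error[rec$group == "b"]
  expect_equal(st$levene_p, levene_test(ea, eb)$p, tolerance = 1e-12)
  want_eq <- st$levene_p > 0.05
  ref <- independent_t(eb, ea, equal_var = want_eq)
  expect_equal(st$t, ref$t, tolerance = 1e-12)
})

test_that("the permutation threshold is reproducible and bounded", {
  fx <- make_transfer_fixture(n_tasks = 4L, seed = 21L)
  models <- lapply(colnames(fx$scores_a), function(t)
    c("region_001", "region_003", "time_post_stroke"))
  names(models) <- colnames(fx$scores_a)
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  null1 <- permutation_familywise_threshold(rec, n_perm = 300L, seed = 5L)
  null2 <- permutation_familywise_threshold(rec, n_perm = 300L, seed = 5L)
  expect_identical(null1$min_p, null2$min_p)
  expect_gt(null1$corrected_alpha, 0)
  expect_lte(null1$corrected_alpha, 0.05)
  # multi-task correction is stricter than none, looser than Bonferroni
  expect_gt(null1$corrected_alpha, 0.05 / (4 * 10))
  expect_warning(permutation_familywise_threshold(rec, n_perm = 50L,
                                                  seed = 1L), "coarse")
})

test_that("a single-task family needs essentially no correction", {
  fx <- make_transfer_fixture(n_tasks = 1L, seed = 31L)
  models <- list(task_01 = c("region_001", "time_post_stroke"))
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  null <- permutation_familywise_threshold(rec, n_perm = 2000L, seed = 2L)
  # min over one statistic is the statistic: corrected alpha ~ 0.05
  expect_gt(null$corrected_alpha, 0.03)
  expect_lte(null$corrected_alpha, 0.05)
})

test_that("random-model consistency reports a bounded fraction", {
  fx <- make_transfer_fixture(lambda = 1.5, seed = 17L)
  sets <- sample_random_feature_sets(30L, c(2L, 8L),
                                     colnames(fx$table_a), seed = 3L)
  res <- random_model_consistency(sets, fx$table_a, fx$scores_a,
                                  fx$table_b, fx$scores_b,
                                  tasks_of_interest = "task_01",
                                  corrected_alpha = 0.05)
  expect_gte(res$fraction, 0)
  expect_lte(res$fraction, 1)
  expect_identical(res$n_tests, 30L)
  expect_true(res$opposite_count >= 0)
  expect_identical(res$per_task$task, "task_01")
})

test_that("the history screen skips sparse cells and finds planted signal", {
  fx <- make_transfer_fixture(seed = 23L)
  models <- list(task_01 = c("region_001", "time_post_stroke"))
  rec <- transfer_predict(models, fx$table_a, fx$scores_a,
                          fx$table_b, fx$scores_b)
  hist <- fx$cohort$history
  # a field with too few responses is skipped and logged
  hist$sparse_field <- NA_real_
  hist$sparse_field[hist$id == "b_001"] <- 1
  res <- history_screen(hist, rec, "task_01")
  expect_true("sparse_field" %in% res$skipped$field)
  expect_false("sparse_field" %in% res$table$field)
  # a field built to correlate with the errors is detected
  eb <- rec[rec$group == "b", ]
  set.seed(9)
  planted <- hist
  planted$planted <- NA_real_
  planted$planted[match(eb$id, planted$id)] <-
    scale(eb$error)[, 1] * 0.9 + rnorm(nrow(eb), 0, sqrt(1 - 0.81))
  res2 <- history_screen(planted, rec, "task_01")
  row <- res2$table[res2$table$field == "planted", ]
  expect_lt(row$p, 0.01)
})
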