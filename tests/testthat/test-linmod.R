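test_that("least squares recovers exact linear relationships", {
  fit <- fit_linear_model(matrix(c(0, 1, 2), 3), c(1, 3, 5))
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  set.seed(1)
  X <- matrix(rnorm(40), 10)
  y <- 2 + X %*% c(1, -3, 0.5, 2)
  fit <- fit_linear_model(X, y)
  expect_lt(max(abs(lesionprog:::predict_linear(fit, X) - y)), 1e-10)
  expect_error(fit_linear_model(matrix(0, 0, 1), numeric(0)), "empty")
})

test_that("rank-deficient fits return the minimum-norm solution", {
  set.seed(2)
  x <- rnorm(5)
  X <- cbind(a = x, b = x, c = rnorm(5))  # duplicated predictor
  y <- 1 + 3 * x + 2 * X[, "c"] + rnorm(5, 0, 0.01)
  fit <- fit_linear_model(X, y)
  # duplicates share the weight equally
  expect_equal(fit$coefficients[["a"]], fit$coefficients[["b"]],
               tolerance = 1e-8)
  # agrees with an independent pseudoinverse oracle
  A <- cbind(1, X)
  beta <- drop(MASS::ginv(A) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), beta,
               tolerance = 1e-8)
})

test_that("LOOCV predictions never use the held-out response", {
  set.seed(3)
  X <- matrix(rnorm(14), 7)
  colnames(X) <- c("f1", "f2")
  y <- rnorm(7)
  tab <- as.data.frame(X)
  p1 <- loocv_predictions(c("f1", "f2"), tab, y)
  y2 <- y
  y2[4] <- y2[4] + 100  # perturb one held-out response
  p2 <- loocv_predictions(c("f1", "f2"), tab, y2)
  expect_equal(p1[4], p2[4], tolerance = 1e-10)
  # exact hyperplane: LOOCV reproduces the truth
  yh <- 1 + X %*% c(2, -1)
  expect_equal(loocv_predictions(c("f1", "f2"), tab, drop(yh)), drop(yh),
               tolerance = 1e-8)
})

test_that("LOOCV matches the brute-force refit oracle", {
  set.seed(4)
  X <- matrix(rnorm(14), 7)
  colnames(X) <- c("f1", "f2")
  y <- rnorm(7)
  expect_equal(loocv_predictions(c("f1", "f2"), as.data.frame(X), y),
               oracle_loocv(X, y), tolerance = 1e-10)
  # larger full-rank case exercising the closed-form path
  X2 <- matrix(rnorm(120), 30)
  colnames(X2) <- paste0("f", 1:4)
  y2 <- rnorm(30)
  expect_equal(loocv_predictions(colnames(X2), as.data.frame(X2), y2),
               oracle_loocv(X2, y2), tolerance = 1e-10)
})

test_that("the selection criterion is the mean absolute error", {
  expect_equal(selection_criterion(c(1, 2), c(1, 2)), 0)
  expect_equal(selection_criterion(c(3, 0), c(1, 2)), 2)
  set.seed(5)
  p <- rnorm(20); y <- rnorm(20)
  expect_equal(selection_criterion(p, y), sum(abs(p - y)) / 20)
  expect_equal(selection_criterion(p, y, "rmse"),
               sqrt(sum((p - y)^2) / 20))
  expect_error(selection_criterion(numeric(0), numeric(0)), "non-empty")
})

test_that("feature search recovers a known sparse support", {
  set.seed(6)
  n <- 40L
  tab <- as.data.frame(matrix(rnorm(n * 20), n))
  colnames(tab) <- sprintf("f%d", 1:20)
  tab$time_post_stroke <- runif(n, 3, 60)
  y <- 3 + 2 * tab$f3 - 4 * tab$f7
  model <- select_features(tab, y)
  expect_true(all(c("f3", "f7") %in% model$features))
  expect_lte(model$criterion, 1e-6)
  # trace criterion strictly decreases at every accepted step
  expect_true(all(diff(model$trace$criterion) < 0))
})

test_that("feature search never ends worse than the seed model", {
  set.seed(7)
  n <- 25L
  tab <- as.data.frame(matrix(rnorm(n * 10), n))
  colnames(tab) <- sprintf("f%d", 1:10)
  tab$time_post_stroke <- runif(n, 3, 60)
  y <- rnorm(n)  # independent of everything
  model <- select_features(tab, y)
  seed_crit <- selection_criterion(
    loocv_predictions("time_post_stroke", tab, y), y)
  expect_lte(model$criterion, seed_crit + 1e-12)
  expect_error(select_features(tab, rep(NA_real_, n)), "missing")
})

test_that("search terminates with monotone traces on random instances", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(15:30, 1)
    p <- sample(5:12, 1)
    tab <- as.data.frame(matrix(rnorm(n * p), n))
    colnames(tab) <- sprintf("f%d", seq_len(p))
    tab$time_post_stroke <- runif(n, 3, 60)
    y <- rnorm(n) + if (runif(1) < 0.5) 2 * tab$f1 else 0
    model <- select_features(tab, y)
    expect_true(all(diff(model$trace$criterion) < 0))
    expect_gte(model$criterion, 0)
  }
})

test_that("random feature sets respect bounds and are uniform", {
  labels <- sprintf("p%03d", 1:50)
  sets <- sample_random_feature_sets(400L, c(2L, 40L), labels, seed = 9L)
  sizes <- lengths(sets)
  expect_true(all(sizes >= 2L & sizes <= 40L))
  expect_true(all(unlist(sets) %in% labels))
  expect_true(all(!vapply(sets, anyDuplicated, integer(1))))
  sets2 <- sample_random_feature_sets(400L, c(2L, 40L), labels, seed = 9L)
  expect_identical(sets, sets2)
  # label usage approximately uniform
  tab <- table(factor(unlist(sets), levels = labels))
  gof <- suppressWarnings(chisq.test(tab))
  expect_gt(gof$p.value, 0.001)
  expect_error(sample_random_feature_sets(5L, c(0L, 4L), labels), "range")
  expect_error(sample_random_feature_sets(5L, c(2L, 60L), labels), "range")
})
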