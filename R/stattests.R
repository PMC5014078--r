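#' Independent-samples t-test
#'
#' Two-sided t-test for a difference in means.  The pooled-variance
#' (equal-variance) form is the default, as appropriate after a
#' variance-homogeneity pre-check; Welch's form is available with
#' `equal_var = FALSE`.  The statistic's numerator is `mean(a) - mean(b)`.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param equal_var pool the variances (default `TRUE`).
#' @return List with `t`, `p`, `df`.
#' @export
independent_t <- function(a, b, equal_var = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group",
                                             call. = FALSE)
  if (equal_var) {
    t_from_summary(length(a), mean(a), sd(a), length(b), mean(b), sd(b))
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter))
  }
}

#' Pooled-variance t-test from summary statistics
#'
#' Computes the independent-samples equal-variance t-test from group
#' sizes, means and SDs alone, so published summary tables can be checked
#' directly.
#'
#' @param n1,m1,s1 size, mean and SD of the first sample.
#' @param n2,m2,s2 size, mean and SD of the second sample.
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
t_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  stopifnot(n1 >= 2L, n2 >= 2L)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Levene's test for equality of variances
#'
#' Classic Levene form: a one-way ANOVA on the absolute deviations from
#' each group's mean.  Used as a pre-check before assuming equal
#' variances in the pooled t-test.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group",
                                             call. = FALSE)
  z <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (var(z) == 0) {
    if (all(z == 0)) return(list(F = 0, p = 1, df1 = 1L,
                                 df2 = length(z) - 2L))
    stop("degenerate (constant) absolute deviations", call. = FALSE)
  }
  fit <- anova(lm(z ~ g))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       df1 = fit$Df[1L], df2 = fit$Df[2L])
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test for a location shift.  The z statistic is
#' computed from the tie-corrected normal approximation of the rank-sum
#' statistic; the p-value is exact (enumeration) for small untied
#' samples and otherwise uses the same normal approximation, following
#' the standard convention of [stats::wilcox.test()].
#'
#' @param a,b numeric samples.
#' @return List with `z`, `p`, `W` (Mann-Whitney U for sample `a`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty",
                               call. = FALSE)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(r)
  tie_term <- sum(nt^3 - nt)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sigma2 <= 0) 0 else (W - mu) / sqrt(sigma2)
  has_ties <- any(nt > 1)
  p <- if (sigma2 <= 0) {
    1
  } else if (!has_ties && n1 < 50L && n2 < 50L) {
    suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
  } else {
    2 * pnorm(-abs(z))
  }
  list(z = z, p = min(p, 1), W = W)
}

#' Paired-samples t-test on differences
#'
#' @param differences numeric vector of paired differences (n >= 2).
#' @return List with `t`, `p` (two-sided), `df`, `mean_diff`.
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  if (length(d) < 2L) stop("need at least 2 paired differences",
                           call. = FALSE)
  s <- sd(d)
  if (s == 0) stop("zero-variance differences: t undefined", call. = FALSE)
  t <- mean(d) / (s / sqrt(length(d)))
  list(t = t, p = 2 * pt(-abs(t), length(d) - 1L), df = length(d) - 1L,
       mean_diff = mean(d))
}
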