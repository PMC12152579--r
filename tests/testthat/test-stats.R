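test_that("identical or degenerate groups give statistic 0 and p 1", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)

  const <- compare_groups(rep(2, 5), rep(2, 6))
  expect_equal(const$statistic, 0)
  expect_equal(const$p, 1)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("the gated t branch matches the textbook pooled-variance formula", {
  set.seed(14)
  x <- rnorm(12, 50, 4)
  y <- rnorm(18, 53, 4)
  cmp <- compare_groups(x, y)
  expect_identical(cmp$test_used, "t")
  oracle <- pooled_t_oracle(x, y)
  expect_equal(cmp$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(cmp$p, oracle$p, tolerance = 1e-10)
})

test_that("non-normal data routes to Mann-Whitney and U matches pair enumeration", {
  set.seed(23)
  x <- exp(rnorm(25, 0, 1.6)) # strongly lognormal: Shapiro fails
  y <- rnorm(30, 2, 1)
  cmp <- compare_groups(x, y)
  expect_identical(cmp$test_used, "mann_whitney")
  expect_lt(cmp$gates$shapiro_a, 0.05)
  expect_equal(cmp$statistic, mwu_oracle(x, y))
  # tied data still matches the midrank U
  xt <- c(1, 2, 2, 3, 5, 5, 6)
  yt <- c(2, 2, 4, 5, 7, 8)
  cmpt <- compare_groups(xt, yt, method = "mann_whitney")
  expect_equal(cmpt$statistic, mwu_oracle(xt, yt))
})

test_that("gated comparison holds its nominal type-I error under a normal null", {
  set.seed(37)
  nrep <- 2000
  rej <- mean(replicate(nrep, {
    compare_groups(rnorm(45), rnorm(100))$p < 0.05
  }))
  band <- 2.576 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rej - 0.05), band)
})

test_that("trajectory regression recovers exact lines and matches the normal equations", {
  x <- seq(20, 70, length.out = 15)
  fit <- fit_trajectory(x, 2 - 0.04 * x)
  expect_equal(fit$slope, -0.04, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  expect_equal(fit$p, 0)

  set.seed(51)
  xr <- runif(25, 0, 10)
  yr <- 1.5 - 0.03 * xr + rnorm(25, 0, 0.1)
  fr <- fit_trajectory(xr, yr)
  sxx <- sum((xr - mean(xr))^2)
  b <- sum((xr - mean(xr)) * (yr - mean(yr))) / sxx
  a <- mean(yr) - b * mean(xr)
  expect_equal(fr$slope, b, tolerance = 1e-10)
  expect_equal(fr$intercept, a, tolerance = 1e-10)
  expect_equal(fr$r, cor(xr, yr), tolerance = 1e-12)
  expect_equal(fr$p, cor.test(xr, yr)$p.value, tolerance = 1e-10)

  # degenerate cases
  expect_error(fit_trajectory(rep(1, 5), rnorm(5)), "Zero-variance")
  flat <- fit_trajectory(xr, rep(1.4, 25))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)
  expect_equal(flat$p, 1)
  expect_error(fit_trajectory(c(1, 2), c(1, 2)), "at least 3")
  expect_message(fit_trajectory(c(xr, NA), c(yr, 1)), "1 non-finite")
})

test_that("tidy and glance expose the trajectory fit as tibbles", {
  set.seed(52)
  fit <- fit_trajectory(runif(20, 20, 70), rnorm(20, 1.4, 0.1), group = "hc")
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_identical(g$group, "hc")
  expect_identical(g$n, 20L)
  td <- tidy(fit)
  expect_equal(td$estimate[2], fit$slope)
})

test_that("slope comparison follows its formula, is antisymmetric, and tracks the pooled model", {
  set.seed(61)
  x1 <- runif(45, -10, 10)
  y1 <- 1.45 + 0.02 * x1 + rnorm(45, 0, 0.12)
  x2 <- runif(100, -10, 10)
  y2 <- 1.40 - 0.01 * x2 + rnorm(100, 0, 0.12)
  fa <- fit_trajectory(x1, y1, group = "hc")
  fb <- fit_trajectory(x2, y2, group = "hiv")
  sc <- compare_slopes(fa, fb)
  oracle <- slope_test_oracle(x1, y1, x2, y2)
  expect_equal(sc$t, oracle$t, tolerance = 1e-10)
  expect_identical(sc$df, oracle$df)
  expect_equal(sc$p, oracle$p, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- compare_slopes(fa, fa)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # swapping group order flips t, keeps p
  rev <- compare_slopes(fb, fa)
  expect_equal(rev$t, -sc$t, tolerance = 1e-12)
  expect_equal(rev$p, sc$p, tolerance = 1e-12)

  # approximate agreement with the group x predictor interaction term
  d <- data.frame(
    x = c(x1, x2), y = c(y1, y2),
    g = rep(c("a", "b"), c(45, 100))
  )
  t_int <- summary(lm(y ~ x * g, d))$coefficients["x:gb", "t value"]
  expect_equal(sign(-t_int), sign(sc$t))
  expect_lt(abs(abs(sc$t) - abs(t_int)) / abs(t_int), 0.25)

  # degenerate fit propagates an error
  flat <- fit_trajectory(x1, rep(1.4, 45))
  expect_error(compare_slopes(fa, flat), "Degenerate")
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  set.seed(71)
  n <- 60
  Z <- cbind(sex = rbinom(n, 1, 0.5), extra = rnorm(n))
  x <- rnorm(n) + 0.5 * Z[, 1]
  y <- 0.4 * x + rnorm(n) - 0.3 * Z[, 2]
  for (m in c("pearson", "spearman")) {
    got <- partial_correlation(x, y, Z, method = m)
    want <- pcor_oracle(x, y, Z, method = m)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$df, n - 4)
  }
})

test_that("partial correlation edge cases behave as documented", {
  set.seed(72)
  x <- rnorm(30)
  y <- rnorm(30)
  # zero covariates reduces exactly to the plain correlation
  plain <- partial_correlation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-14)
  expect_equal(plain$p_value, cor.test(x, y)$p.value, tolerance = 1e-12)

  # an orthogonal covariate changes nothing (up to numerical noise)
  z <- rnorm(30)
  z_orth <- lm.fit(cbind(1, x, y), z)$residuals
  with_cov <- partial_correlation(x, y, z_orth)
  expect_equal(with_cov$r, cor(x, y), tolerance = 1e-10)

  # y = x exactly: r = 1 regardless of covariates
  expect_equal(partial_correlation(x, x, z)$r, 1, tolerance = 1e-12)

  # constant covariate dropped with a warning; duplicate column is an error
  expect_warning(partial_correlation(x, y, rep(1, 30)), "constant")
  expect_error(
    suppressWarnings(partial_correlation(x, y, cbind(z, z))),
    "Rank-deficient"
  )
})

test_that("BH adjustment equals the step-up definition and its invariants", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(81)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # monotone in the ranks
  }
})
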