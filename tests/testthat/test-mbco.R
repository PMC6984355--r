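m <- two_mediator_model()

test_that("all three methods share the same statistic; p-values differ
           only in the reference distribution", {
  d <- simulate_mediation(150, c(b1 = .4, b2 = .4, b3 = .4), seed = 61)
  ta <- mbco_test(m, d, "asymptotic")
  tp <- mbco_test(m, d, "parametric", R = 50, seed = 1)
  ts <- mbco_test(m, d, "semiparametric", R = 50, seed = 1)
  expect_equal(tp$statistic, ta$statistic)
  expect_equal(ts$statistic, ta$statistic)
  expect_equal(ta$df, 1L)
  expect_equal(ta$p_value,
               pchisq(ta$statistic, 1, lower.tail = FALSE))
  expect_gte(ta$statistic, 0)
  # LRT agrees with the independent lm branch oracle
  expect_equal(ta$statistic,
               -2 * (oracle_null_ll(d) - oracle_full_ll(d)),
               tolerance = 1e-8)
})

test_that("bootstrap p-value is the proportion of null draws above the
           observed statistic and is monotone in it", {
  d <- simulate_mediation(100, c(b1 = 0, b2 = .4, b3 = .4), seed = 62)
  tb <- mbco_test(m, d, "parametric", R = 199, seed = 5)
  expect_equal(length(tb$null_sample) + tb$n_boot_failures, 199L)
  expect_equal(tb$p_value, mean(tb$null_sample > tb$statistic))
  # holding the null sample fixed, a larger observed T never raises p
  p_at <- vapply(c(0, 1, 2, 5), function(t0) mean(tb$null_sample > t0), 0)
  expect_true(all(diff(p_at) <= 0))
  # near-zero observed statistic => p near 1
  expect_gte(mean(tb$null_sample > 0), mean(tb$null_sample > 1e-9) - 1e-12)
})

test_that("R = 0 and unconstrained models are rejected", {
  d <- simulate_mediation(50, c(b1 = .3), seed = 63)
  expect_error(mbco_test(m, d, "parametric", R = 0), "positive")
  m_nc <- path_model(c("M1 ~ b1*X"))
  expect_error(mbco_test(m_nc, d[c("X", "M1")]), "constraint")
})

test_that("semi-parametric transform forces the sample covariance onto the
           null-implied covariance", {
  for (s in 71:73) {
    d <- simulate_mediation(200, c(b1 = .4, b2 = .3, b3 = .2), seed = s)
    f0 <- fit_null(m, d)
    ystar <- null_transform(m, d, f0)
    mom0 <- implied_moments(m, f0$params)
    expect_lt(max(abs(cov(ystar) - mom0$cov)), 1e-10)
    expect_equal(unname(colMeans(ystar)), unname(mom0$mean),
                 tolerance = 1e-10)
  }
})

test_that("when the implied covariance equals the sample covariance the
           transform is the identity", {
  d <- simulate_mediation(80, c(b1 = .4, b2 = .4, b3 = .4), seed = 74)
  n <- nrow(d)
  # a saturated recursive model reproduces the ML covariance S*(n-1)/n;
  # inflating its residual variances by n/(n-1) makes the implied
  # covariance equal S itself, under which the map must be the identity
  f <- fit_full(m, d)
  f$params$psi <- f$params$psi * n / (n - 1)
  ystar <- null_transform(m, d, f)
  expect_equal(unname(ystar), unname(as.matrix(d)[, c("X", "M1", "M2", "Y")]),
               tolerance = 1e-8)
})

test_that("two bootstrap seeds give p-values within resampling error", {
  d <- simulate_mediation(120, c(b1 = .2, b2 = .3, b3 = .3), seed = 75)
  p1 <- mbco_test(m, d, "semiparametric", R = 199, seed = 1)$p_value
  p2 <- mbco_test(m, d, "semiparametric", R = 199, seed = 2)$p_value
  expect_lt(abs(p1 - p2), 5 * sqrt(0.25 * 2 / 199))
})

test_that("parametric bootstrap p-values are approximately uniform under a
           regular null", {
  # b1 = 0, b2 = b3 nonzero: a regular point of the constraint set
  set.seed(660)
  ps <- replicate(150, {
    d <- simulate_mediation(200, c(b1 = 0, b2 = .39, b3 = .39))
    mbco_test(m, d, "parametric", R = 99)$p_value
  })
  # bootstrap p-values are discrete on k/R; suppress the KS ties warning
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
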