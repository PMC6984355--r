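m <- two_mediator_model()

test_that("percentile bootstrap interval matches an independent lm-based
           replication of the same resampling stream", {
  d <- simulate_mediation(60, c(b1 = .4, b2 = .4, b3 = .4), seed = 81)
  ci <- percentile_boot_ci(m, d, R = 200, level = 0.95, seed = 99)
  # replicate the resampling with the same RNG stream, products via lm()
  set.seed(99)
  n <- nrow(d)
  prods <- vapply(1:200, function(r) {
    db <- d[sample.int(n, n, replace = TRUE), ]
    coef(lm(M1 ~ X, db))["X"] * coef(lm(M2 ~ M1 + X, db))["M1"] *
      coef(lm(Y ~ M2 + M1 + X, db))["M2"]
  }, 0)
  s <- sort(prods)
  # type-7 quantile by hand
  q7 <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(ci$lower, q7(0.025), tolerance = 1e-10)
  expect_equal(ci$upper, q7(0.975), tolerance = 1e-10)
  expect_identical(ci$rejects_zero, ci$lower > 0 || ci$upper < 0)
})

test_that("degenerate resamples with a constant outcome give a [0, 0]
           interval that does not reject", {
  set.seed(82)
  d <- data.frame(X = rnorm(40), M1 = rnorm(40), M2 = rnorm(40), Y = 0)
  ci <- percentile_boot_ci(m, d, R = 50, seed = 1)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 0)
  expect_false(ci$rejects_zero)
})

test_that("coefficient covariance is block-diagonal and matches lm within
           equations", {
  d <- simulate_mediation(90, c(b1 = .4, b2 = .4, b3 = .4), seed = 83)
  f <- fit_full(m, d)
  V <- f$vcov_beta
  expect_equal(V["b1", "b2"], 0)
  expect_equal(V["b2", "b3"], 0)
  expect_equal(V["b1", "b3"], 0)
  l2 <- lm(M2 ~ M1 + X, d)
  n <- nrow(d)
  Vlm <- summary(l2)$cov.unscaled * sum(resid(l2)^2) / n
  expect_equal(V["b2", "b4"], Vlm["M1", "X"], tolerance = 1e-10)
  expect_equal(V["b2", "b2"], Vlm["M1", "M1"], tolerance = 1e-10)
})

test_that("Monte Carlo interval matches a brute-force product simulation
           and degenerates correctly", {
  d <- simulate_mediation(200, c(b1 = .4, b2 = .4, b3 = .4), seed = 84)
  f <- fit_full(m, d)
  ci <- monte_carlo_ci(f, draws = 2e5, seed = 7)
  mu <- coef(f)[c("b1", "b2", "b3")]
  V <- f$vcov_beta[c("b1", "b2", "b3"), c("b1", "b2", "b3")]
  set.seed(1234)   # independent draw stream
  pr <- rnorm(1e6, mu[1], sqrt(V[1, 1])) *
    rnorm(1e6, mu[2], sqrt(V[2, 2])) * rnorm(1e6, mu[3], sqrt(V[3, 3]))
  qo <- quantile(pr, c(0.025, 0.975), names = FALSE)
  expect_equal(ci$lower, qo[1], tolerance = 4e-3)
  expect_equal(ci$upper, qo[2], tolerance = 4e-3)
  # zero covariance: interval collapses to the point estimate
  f0 <- f; f0$vcov_beta[] <- 0
  ci0 <- monte_carlo_ci(f0)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, prod(mu))
})

test_that("profile-likelihood endpoints solve the -2*deltaLL = chi-square
           criterion and bracket the MLE", {
  d <- simulate_mediation(150, c(b1 = .4, b2 = .4, b3 = .4), seed = 85)
  ci <- profile_likelihood_ci(m, d, level = 0.95)
  f1 <- fit_full(m, d)
  crit <- qchisq(0.95, 1)
  for (ep in c(ci$lower, ci$upper)) {
    f0 <- fit_null(m, d, constant = ep)
    expect_lt(abs(-2 * (f0$log_likelihood - f1$log_likelihood) - crit),
              1e-4)
  }
  expect_lt(ci$lower, ci$point_estimate)
  expect_gt(ci$upper, ci$point_estimate)
})

test_that("Monte Carlo interval width shrinks like n^{-1/2}", {
  w <- vapply(c(200, 800), function(n) {
    d <- simulate_mediation(n, c(b1 = .4, b2 = .4, b3 = .4), seed = 86)
    ci <- monte_carlo_ci(fit_full(m, d), draws = 5e4, seed = 2)
    ci$upper - ci$lower
  }, 0)
  expect_gt(w[1] / w[2], 1.5)
  expect_lt(w[1] / w[2], 2.7)
})
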