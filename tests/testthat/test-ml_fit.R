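m <- two_mediator_model()

test_that("full-model MLE equals per-equation least squares", {
  d <- simulate_mediation(120, c(b1 = .4, b2 = .3, b3 = .5), seed = 11)
  f <- fit_full(m, d)
  l1 <- lm(M1 ~ X, d); l2 <- lm(M2 ~ M1 + X, d); l3 <- lm(Y ~ M2 + M1 + X, d)
  expect_equal(unname(coef(f)[c("b1")]), unname(coef(l1)["X"]))
  expect_equal(unname(coef(f)[c("b2", "b4")]),
               unname(coef(l2)[c("M1", "X")]))
  expect_equal(unname(coef(f)[c("b3", "b5", "b6")]),
               unname(coef(l3)[c("M2", "M1", "X")]))
  expect_equal(f$log_likelihood, oracle_full_ll(d))
})

test_that("conditional and joint likelihood routes agree, and match a
           direct multivariate-normal density", {
  d <- simulate_mediation(60, c(b1 = .3, b2 = .3, b3 = .3), seed = 12)
  pr <- chain_params(0.25)
  pr$alpha[] <- c(0.1, -0.2, 0.3, 0)
  ll_c <- loglik_path(m, pr, d, method = "conditional")
  ll_j <- loglik_path(m, pr, d, method = "joint")
  expect_equal(ll_c, ll_j, tolerance = 1e-10)
  # independent route: solve/det rather than Cholesky
  mom <- implied_moments(m, pr)
  Y <- as.matrix(d)[, c("X", "M1", "M2", "Y")]
  md <- mahalanobis(Y, mom$mean, mom$cov)
  ll_o <- -0.5 * sum(md) -
    nrow(Y) / 2 * (4 * log(2 * pi) + log(det(mom$cov)))
  expect_equal(ll_c, ll_o, tolerance = 1e-8)
  # invariance to row order
  expect_equal(loglik_path(m, pr, d[rev(seq_len(nrow(d))), ]), ll_c)
})

test_that("one row of zeros under an identity model gives -(p/2) log(2 pi)
           per row", {
  pr <- chain_params(0)
  d10 <- as.data.frame(matrix(0, 10, 4,
                              dimnames = list(NULL, c("X", "M1", "M2", "Y"))))
  expect_equal(loglik_path(m, pr, d10), -10 * 2 * log(2 * pi))
})

test_that("generic numeric optimizer reproduces the closed-form MLE", {
  d <- simulate_mediation(80, c(b1 = .4, b2 = .4, b3 = .4), seed = 13)
  f <- fit_full(m, d)
  g <- mbcolrt:::fit_full_numeric(m, d)
  expect_lt(max(abs(g$params$beta - f$params$beta)), 1e-6)
  expect_equal(g$log_likelihood, f$log_likelihood, tolerance = 1e-8)
})

test_that("null fit matches the branch-enumeration oracle and respects
           nesting", {
  for (s in 21:25) {
    d <- simulate_mediation(50, c(b1 = .3, b2 = 0, b3 = .4), seed = s)
    f1 <- fit_full(m, d)
    f0 <- fit_null(m, d)
    expect_lte(f0$log_likelihood, f1$log_likelihood + 1e-10)
    expect_equal(f0$log_likelihood, oracle_null_ll(d), tolerance = 1e-8)
    expect_lte(f0$constraint_violation, 1e-8)
    expect_true(all(f0$params$psi > 1e-10))
  }
})

test_that("constraining the product to its MLE value reproduces the full
           fit", {
  d <- simulate_mediation(100, c(b1 = .4, b2 = .4, b3 = .4), seed = 31)
  f1 <- fit_full(m, d)
  ihat <- prod(coef(f1)[c("b1", "b2", "b3")])
  f0 <- fit_null(m, d, constant = ihat)
  expect_equal(f0$log_likelihood, f1$log_likelihood, tolerance = 1e-7)
  expect_equal(unname(coef(f0)[c("b1", "b2", "b3")]),
               unname(coef(f1)[c("b1", "b2", "b3")]), tolerance = 1e-4)
})

test_that("nonzero-constant null fit matches a profile-grid brute force", {
  d <- simulate_mediation(50, c(b1 = .4, b2 = .4, b3 = .4), seed = 41)
  const <- 0.02
  f0 <- fit_null(m, d, constant = const)
  # brute force: grid over (b2, b3), b1 = const/(b2*b3), all other
  # parameters re-estimated by lm() with the constrained term as offset
  prof_ll <- function(b1, b2, b3) {
    ll_lm(I(M1 - b1 * X) ~ 1, d) +
      ll_lm(I(M2 - b2 * M1) ~ X, d) +
      ll_lm(I(Y - b3 * M2) ~ M1 + X, d) + ll_exo(d$X)
  }
  g <- expand.grid(b2 = seq(0.05, 0.8, length.out = 60),
                   b3 = seq(0.05, 0.8, length.out = 60))
  vals <- mapply(function(b2, b3) prof_ll(const / (b2 * b3), b2, b3),
                 g$b2, g$b3)
  best <- which.max(vals)
  ref <- optim(c(g$b2[best], g$b3[best]),
               function(p) -prof_ll(const / prod(p), p[1], p[2]),
               control = list(reltol = 1e-14))
  expect_lt(abs(f0$log_likelihood - (-ref$value)), 1e-4)
})

test_that("degenerate inputs raise estimation errors", {
  d <- simulate_mediation(50, c(b1 = .3), seed = 51)
  expect_error(fit_full(m, d[1:4, ]), "too few observations")
  d2 <- d; d2$M2 <- d2$M1            # collinear predictor
  expect_error(fit_full(m, d2), "rank-deficient|collinear")
  d3 <- d; d3$Y[5] <- NA
  expect_error(fit_full(m, d3), "missing")
})
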