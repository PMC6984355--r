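#' MBCO likelihood-ratio tests of an indirect effect
#'
#' Tests the composite null hypothesis that a product of path coefficients
#' (the indirect effect) equals a constant, by comparing the full model
#' against a null model estimated by maximizing the same likelihood subject
#' to the product constraint.  The statistic is
#' `T = -2 (logL_null - logL_full)`, clipped at zero.  Because the
#' constraint set never touches the boundary of the coefficient space, T is
#' asymptotically chi-square with degrees of freedom equal to the number of
#' independent equality constraints (1 here), and the LRT is asymptotically
#' pivotal — unlike the sampling distribution of the estimated product
#' itself, which depends on which coefficient is null.
#'
#' Three reference distributions for T are available:
#' \describe{
#'   \item{asymptotic}{upper-tail chi-square(1) probability at T.}
#'   \item{parametric}{draw `R` samples of size n from the multivariate
#'     normal with the fitted null model's implied mean and covariance,
#'     refit both models to each draw, and take the p-value as the
#'     proportion of bootstrap statistics greater than the observed T.}
#'   \item{semiparametric}{linearly transform the observed rows so their
#'     sample covariance equals the null model's implied covariance (see
#'     [null_transform()]), resample n rows with replacement `R` times,
#'     refit, and form the p-value the same way.  No normality assumption
#'     enters the resampling.}
#' }
#'
#' Bootstrap replications whose refit fails (degenerate resample) are
#' dropped and counted in `n_boot_failures`; the p-value denominator is the
#' number of successes.  `adjust = TRUE` switches to the (b+1)/(R+1)
#' finite-sample form of the p-value.
#'
#' @param model a `path_model` with a declared constraint
#' @param data data.frame or matrix with the model's columns
#' @param method `"asymptotic"`, `"parametric"`, or `"semiparametric"`
#' @param R number of bootstrap replications (bootstrap methods)
#' @param seed optional integer seed for the bootstrap resampling
#' @param adjust use the (b+1)/(R+1) p-value instead of the plain proportion
#' @return object of class `mbco_lrt`: `statistic`, `df`, `p_value`,
#'   `method`, `null_sample` (bootstrap statistics, or `NULL`),
#'   `n_boot_failures`, `fit_full`, `fit_null`
#' @examples
#' m <- two_mediator_model()
#' d <- simulate_mediation(150, c(b1 = .4, b2 = .4, b3 = .4), seed = 7)
#' mbco_test(m, d, method = "asymptotic")
#' @references Wilks likelihood-ratio asymptotics; Bollen-Stine-style
#'   covariance-matching bootstrap transforms.
#' @export
mbco_test <- function(model, data,
                      method = c("asymptotic", "parametric",
                                 "semiparametric"),
                      R = 1000, seed = NULL, adjust = FALSE) {
  method <- match.arg(method)
  if (is.null(model$constraint))
    stop("model has no constraint to test")
  Y <- as_model_matrix(model, data)
  f1 <- fit_full(model, Y)
  f0 <- fit_null(model, Y)
  Tobs <- max(0, -2 * (f0$log_likelihood - f1$log_likelihood))
  df <- 1L
  if (method == "asymptotic") {
    return(new_mbco_lrt(Tobs, df, stats::pchisq(Tobs, df, lower.tail = FALSE),
                        method, NULL, 0L, f1, f0))
  }
  if (R < 1) stop("R must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  constant <- model$constraint$constant
  n <- nrow(Y)
  Tstar <- numeric(R)
  fail <- 0L
  if (method == "parametric") {
    mom0 <- implied_moments(model, f0$params)
    CU <- chol(mom0$cov)
    for (r in seq_len(R)) {
      Yb <- rmvn_chol(n, mom0$mean, CU)
      colnames(Yb) <- model$vars
      Tstar[r] <- lrt_stat_or_na(model, Yb, constant)
      if (is.na(Tstar[r])) fail <- fail + 1L
    }
  } else {
    Ystar <- null_transform(model, Y, f0)
    for (r in seq_len(R)) {
      Yb <- Ystar[sample.int(n, n, replace = TRUE), , drop = FALSE]
      Tstar[r] <- lrt_stat_or_na(model, Yb, constant)
      if (is.na(Tstar[r])) fail <- fail + 1L
    }
  }
  ok <- Tstar[!is.na(Tstar)]
  if (!length(ok)) stop("all bootstrap refits failed")
  result_flag <- fail > 0.1 * R
  p <- if (adjust) (sum(ok > Tobs) + 1) / (length(ok) + 1) else
    mean(ok > Tobs)
  out <- new_mbco_lrt(Tobs, df, p, method, ok, fail, f1, f0)
  out$excess_failures <- result_flag
  if (result_flag)
    warning("more than 10% of bootstrap refits failed (", fail, " of ", R,
            ")")
  out
}

new_mbco_lrt <- function(stat, df, p, method, null_sample, fail, f1, f0) {
  structure(list(
    statistic = stat, df = df, p_value = p,
    method = method, null_sample = null_sample,
    n_boot_failures = fail,
    fit_full = f1, fit_null = f0
  ), class = "mbco_lrt")
}

# Fast LRT statistic for one (bootstrap) dataset: only the constrained
# equations change between null and full fit, so for constant 0
#   T = n * min_i log(ryy_i / (ryy_i - rxy_i^2/rxx_i)).
lrt_stat_or_na <- function(model, Y, constant) {
  tryCatch({
    stats <- fwl_stats(model, Y)
    lrt_from_stats(stats, constant)
  }, error = function(e) NA_real_)
}

lrt_from_stats <- function(stats, constant) {
  bhat <- bc_unconstrained(stats)
  pll_full <- profiled_ll_part(stats, bhat)
  pll_null <- constrained_profile(stats, constant)$pll
  max(0, -2 * (pll_null - pll_full))
}

#' Transform data to match a fitted null model's covariance
#'
#' Given the null-model fit, each centered row is mapped by the linear
#' operator `t(U0) %*% solve(t(Us))`, where `S = t(Us) %*% Us` is the
#' Cholesky factorization of the sample covariance (divisor n-1) and
#' `Sigma0 = t(U0) %*% U0` that of the null model's implied covariance; the
#' null-implied means are then added back.  The sample covariance of the
#' result equals `Sigma0` exactly (up to floating point), so resampling rows
#' with replacement mimics sampling under the null hypothesis without any
#' distributional assumption on the row shapes.  The identity is verified
#' at run time to 1e-10.
#'
#' Means are handled by centering at the sample means before the map and
#' restoring the null-implied means after it: the covariance identity
#' constrains second moments only, and with free intercepts the
#' null-implied means coincide with the sample means.
#'
#' @param model a `path_model`
#' @param data data.frame or matrix
#' @param null_fit an `mbco_fit` from [fit_null()] on the same data
#' @return numeric matrix of transformed rows (same dimensions as the data)
#' @export
null_transform <- function(model, data, null_fit) {
  Y <- as_model_matrix(model, data)
  n <- nrow(Y)
  if (n <= ncol(Y)) stop("need more rows than variables for a positive ",
                         "definite sample covariance")
  S <- stats::cov(Y)
  Us <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite"))
  mom0 <- implied_moments(model, null_fit$params)
  U0 <- chol(mom0$cov)
  ctr <- sweep(Y, 2, colMeans(Y))
  # row vector convention: y*' = y' Us^{-1} U0  <=>  y* = t(U0) Us^{-T} y
  Ystar <- ctr %*% backsolve(Us, U0)
  Ystar <- sweep(Ystar, 2, mom0$mean, `+`)
  dev <- max(abs(stats::cov(Ystar) - mom0$cov))
  if (dev > 1e-10)
    stop("transform self-check failed: max |cov(y*) - Sigma0| = ", dev)
  colnames(Ystar) <- colnames(Y)
  Ystar
}

# n draws from N(mu, Sigma) given the upper Cholesky factor CU of Sigma
rmvn_chol <- function(n, mu, CU) {
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% CU, 2, mu, `+`)
}

#' @export
print.mbco_lrt <- function(x, ...) {
  lab <- c(asymptotic = "Asymptotic MBCO LRT",
           parametric = "Parametric bootstrap MBCO LRT",
           semiparametric = "Semi-parametric bootstrap MBCO LRT")[x$method]
  cat(lab, "\n")
  cat("  T =", format(x$statistic, digits = 6), " df =", x$df,
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$null_sample))
    cat("  bootstrap replications:", length(x$null_sample),
        " (failed:", x$n_boot_failures, ")\n")
  invisible(x)
}
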