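#' Percentile bootstrap confidence interval for the indirect effect
#'
#' Draws `R` with-replacement resamples of the rows, refits the full model
#' to each, and takes the `alpha/2` and `1 - alpha/2` empirical quantiles
#' (type 7, linear interpolation) of the resampled coefficient products as
#' the interval.  The associated test rejects a zero indirect effect iff 0
#' lies outside the interval.
#'
#' @param model a `path_model` with a declared constraint
#' @param data data.frame or matrix
#' @param R number of bootstrap resamples
#' @param level confidence level
#' @param seed optional integer seed
#' @return object of class `mbco_ci` with `lower`, `upper`, `level`,
#'   `method`, `point_estimate`, `rejects_zero`, `n_failures`
#' @export
percentile_boot_ci <- function(model, data, R = 1000, level = 0.95,
                               seed = NULL) {
  if (R < 1) stop("R must be a positive integer")
  if (is.null(model$constraint)) stop("model has no constraint")
  Y <- as_model_matrix(model, data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)
  stats0 <- fwl_stats(model, Y)
  point <- prod(bc_unconstrained(stats0))
  prods <- vapply(seq_len(R), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(prod(bc_unconstrained(fwl_stats(model, Y[idx, , drop = FALSE]))),
             error = function(e) NA_real_)
  }, 0)
  ok <- prods[!is.na(prods)]
  if (!length(ok)) stop("all bootstrap refits failed")
  a <- 1 - level
  q <- stats::quantile(ok, c(a / 2, 1 - a / 2), names = FALSE, type = 7)
  new_mbco_ci(q[1], q[2], level, "percentile", point,
              n_failures = sum(is.na(prods)))
}

#' Monte Carlo confidence interval for the indirect effect
#'
#' Draws `draws` coefficient vectors from the multivariate normal whose
#' mean is the full-model MLEs of the tested coefficients and whose
#' covariance is their asymptotic (observed-information) covariance, forms
#' the product of each draw, and takes the `alpha/2` and `1 - alpha/2`
#' quantiles.  For a recursive model each tested coefficient sits in a
#' different equation, so the covariance is block-diagonal across equations
#' and the tested triplet's covariance has zero off-diagonals.
#'
#' @param fit an `mbco_fit` from [fit_full()]
#' @param draws number of Monte Carlo draws (100,000 by default)
#' @param level confidence level
#' @param seed optional integer seed
#' @return an `mbco_ci` (see [percentile_boot_ci()])
#' @export
monte_carlo_ci <- function(fit, draws = 1e5, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "mbco_fit"))
  model <- fit$model
  if (is.null(model$constraint)) stop("model has no constraint")
  if (is.null(fit$vcov_beta))
    stop("fit carries no coefficient covariance; use fit_full()")
  lab <- model$constraint$labels
  mu <- fit$params$beta[lab]
  V <- fit$vcov_beta[lab, lab, drop = FALSE]
  point <- prod(mu)
  if (max(abs(V)) == 0)
    return(new_mbco_ci(point, point, level, "montecarlo", point))
  CU <- tryCatch(chol(V), error = function(e)
    stop("coefficient covariance is not positive definite"))
  if (!is.null(seed)) set.seed(seed)
  draws_mat <- rmvn_chol(draws, mu, CU)
  prods <- draws_mat[, 1]
  for (j in seq_along(lab)[-1]) prods <- prods * draws_mat[, j]
  a <- 1 - level
  q <- stats::quantile(prods, c(a / 2, 1 - a / 2), names = FALSE, type = 7)
  new_mbco_ci(q[1], q[2], level, "montecarlo", point)
}

#' Profile-likelihood confidence interval for the indirect effect
#'
#' The profile log-likelihood at a candidate value `i` of the indirect
#' effect is the model log-likelihood maximized subject to the product of
#' the tested coefficients equalling `i` (the constrained fit of
#' [fit_null()] with `constant = i`).  The interval endpoints are the
#' smallest and largest `i` at which
#' `-2 (logL_profile(i) - logL_full) = qchisq(level, 1)`
#' (3.841 at the 95% level), found by expanding a bracket outward from the
#' MLE of the product and root-finding within it.  At the returned
#' endpoints the equality holds to 1e-4.
#'
#' @param model a `path_model` with a declared constraint
#' @param data data.frame or matrix
#' @param level confidence level
#' @param n_starts starts for each constrained fit (see [fit_null()])
#' @return an `mbco_ci` (see [percentile_boot_ci()])
#' @export
profile_likelihood_ci <- function(model, data, level = 0.95, n_starts = 3) {
  if (is.null(model$constraint)) stop("model has no constraint")
  Y <- as_model_matrix(model, data)
  stats <- fwl_stats(model, Y, check_rank = TRUE)
  bhat <- bc_unconstrained(stats)
  pll_full <- profiled_ll_part(stats, bhat)
  point <- prod(bhat)
  crit <- stats::qchisq(level, 1)
  tfun <- function(i) {
    pll0 <- constrained_profile(stats, i, n_starts)$pll
    max(0, -2 * (pll0 - pll_full))
  }
  lower <- profile_endpoint(tfun, point, crit, direction = -1)
  upper <- profile_endpoint(tfun, point, crit, direction = +1)
  new_mbco_ci(lower, upper, level, "profile", point)
}

# Walk outward from the product MLE until T(i) crosses crit, then root-find.
profile_endpoint <- function(tfun, point, crit, direction) {
  bound <- 10 * abs(point) + 1
  step <- max(abs(point) / 8, 0.02)
  x_in <- point; t_in <- 0
  x_out <- point
  t_prev <- 0
  repeat {
    x_out <- x_out + direction * step
    if (abs(x_out - point) > bound)
      stop("no profile-likelihood bracket found within ", bound,
           " of the estimate; profile may be too flat")
    t_out <- tfun(x_out)
    if (t_out < t_prev - 1e-8)
      warning("profile likelihood non-monotone along the search path")
    if (t_out >= crit) break
    x_in <- x_out; t_in <- t_out
    t_prev <- t_out
    step <- step * 2
  }
  lo <- min(x_in, x_out); hi <- max(x_in, x_out)
  f_lo <- if (lo == x_in) t_in - crit else t_out - crit
  f_hi <- if (hi == x_in) t_in - crit else t_out - crit
  root <- stats::uniroot(function(i) tfun(i) - crit,
                         lower = lo, upper = hi,
                         f.lower = f_lo, f.upper = f_hi,
                         tol = 1e-10, maxiter = 200)
  root$root
}

new_mbco_ci <- function(lower, upper, level, method, point,
                        n_failures = 0L) {
  structure(list(
    lower = lower, upper = upper, level = level, method = method,
    point_estimate = point,
    rejects_zero = (0 < lower) || (0 > upper),
    n_failures = n_failures
  ), class = "mbco_ci")
}

#' @export
print.mbco_ci <- function(x, ...) {
  lab <- c(percentile = "Percentile bootstrap CI",
           montecarlo = "Monte Carlo CI",
           profile = "Profile-likelihood CI")[x$method]
  cat(lab, sprintf("(%d%%)\n", round(100 * x$level)))
  cat(sprintf("  estimate %.4f, interval [%.4f, %.4f]%s\n",
              x$point_estimate, x$lower, x$upper,
              if (x$rejects_zero) "  (excludes 0)" else ""))
  invisible(x)
}
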