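## Maximum-likelihood fitting of recursive path models, unconstrained and
## under the product constraint g(beta) = b_1 b_2 ... b_K = c.
##
## For a recursive model with independent residuals the joint normal
## likelihood factors into per-equation conditional regressions plus
## exogenous marginals, so the unconstrained MLE is equation-by-equation
## least squares with divisor-n residual variances.  For the constrained
## fit, all parameters except the K constrained coefficients can be
## concentrated out in closed form (Frisch-Waugh-Lovell): projecting the
## response and the constrained predictor of each equation onto the span of
## the remaining regressors reduces each equation's profiled RSS to a
## quadratic in its constrained coefficient,
##   RSS_i(b) = ryy_i - 2 b rxy_i + b^2 rxx_i,
## leaving a K-dimensional profiled likelihood that is maximized exactly on
## the constraint set: for c = 0 the set is the union of the K hyperplanes
## b_i = 0 (each branch closed form); for c != 0 one coefficient is
## eliminated and the remaining K-1 coordinates optimized numerically with
## multiple starts.

# Per-dataset sufficient statistics.  Y must be a numeric matrix whose
# columns cover model$vars (topological order not required; indexed by name).
fwl_stats <- function(model, Y, check_rank = FALSE) {
  n <- nrow(Y)
  cons_labels <- if (!is.null(model$constraint)) model$constraint$labels
  eqs <- vector("list", length(model$equations))
  names(eqs) <- names(model$equations)
  for (v in names(model$equations)) {
    lab <- model$equations[[v]]
    ci <- which(lab %in% cons_labels)
    if (length(ci) > 1L)
      stop("constrained coefficients must lie in distinct equations ",
           "(equation for ", v, " has ", length(ci), ")")
    X <- cbind(`(Intercept)` = 1, Y[, names(lab), drop = FALSE])
    if (n <= ncol(X))
      stop("too few observations (n = ", n, ") to fit equation for ", v,
           " with ", ncol(X), " parameters")
    if (check_rank && qr(X)$rank < ncol(X))
      stop("rank-deficient design in equation for ", v)
    y <- Y[, v]
    if (length(ci) == 1L) {
      xc <- X[, 1L + ci]
      Z <- X[, -(1L + ci), drop = FALSE]
      B <- solve(crossprod(Z), crossprod(Z, cbind(y, xc)))
      res <- cbind(y, xc) - Z %*% B
      eqs[[v]] <- list(
        type = "constrained", label = unname(lab[ci]),
        cons_pred = names(lab)[ci],
        other_labels = unname(lab[-ci]), other_preds = names(lab)[-ci],
        bz = B,
        ryy = sum(res[, 1]^2), rxy = sum(res[, 1] * res[, 2]),
        rxx = sum(res[, 2]^2))
      if (eqs[[v]]$rxx <= 0)
        stop("constrained predictor ", names(lab)[ci],
             " is collinear with the other regressors in equation for ", v)
    } else {
      B <- solve(crossprod(X), crossprod(X, y))
      rss <- sum((y - X %*% B)^2)
      eqs[[v]] <- list(type = "free", labels = unname(lab),
                       preds = names(lab), coef = drop(B), rss = rss)
    }
  }
  exo <- lapply(model$exogenous, function(v) {
    m <- mean(Y[, v])
    list(mean = m, var = sum((Y[, v] - m)^2) / n)
  })
  names(exo) <- model$exogenous
  list(n = n, eqs = eqs, exo = exo,
       cons_eqs = names(model$equations)[vapply(eqs, function(e)
         e$type == "constrained", TRUE)])
}

rss_quad <- function(eq, b) eq$ryy - 2 * b * eq$rxy + b^2 * eq$rxx

# Profiled log-likelihood contribution of the constrained equations at
# constrained-coefficient values bc (named by equation).  Other equations
# and exogenous marginals do not depend on bc.
profiled_ll_part <- function(stats, bc) {
  n <- stats$n
  ll <- 0
  for (i in seq_along(stats$cons_eqs)) {
    rss <- rss_quad(stats$eqs[[stats$cons_eqs[i]]], bc[i])
    if (rss <= 0) return(-Inf)
    ll <- ll - n / 2 * log(rss / n)
  }
  ll
}

# Unconstrained maximizers of the profiled likelihood (= full-model MLEs of
# the constrained coefficients).
bc_unconstrained <- function(stats) {
  vapply(stats$cons_eqs, function(v) {
    e <- stats$eqs[[v]]
    e$rxy / e$rxx
  }, 0)
}

# Maximize the profiled likelihood subject to prod(bc) = constant.
# Returns list(bc, pll).  For constant 0 the solution is exact (best of the
# K branches b_i = 0); otherwise one coordinate is eliminated and the rest
# optimized by Nelder-Mead from a deterministic multi-start.
constrained_profile <- function(stats, constant, n_starts = 5) {
  K <- length(stats$cons_eqs)
  bhat <- bc_unconstrained(stats)
  if (constant == 0) {
    best <- NULL
    for (i in seq_len(K)) {
      bc <- bhat
      bc[i] <- 0
      pll <- profiled_ll_part(stats, bc)
      if (is.null(best) || pll > best$pll) best <- list(bc = bc, pll = pll)
    }
    return(best)
  }
  if (K == 1L) {
    bc <- constant
    names(bc) <- stats$cons_eqs
    return(list(bc = bc, pll = profiled_ll_part(stats, bc)))
  }
  jitter_factors <- c(0.5, 2, -1, 0.25, 4, -0.5, 1.5)
  best <- NULL
  for (drop_i in seq_len(K)) {
    others <- bhat[-drop_i]
    # keep starts off the removable singularity prod(others) = 0
    others[abs(others) < 1e-3] <- 1e-3 * sign(constant)
    obj <- function(u) {
      pu <- prod(u)
      if (abs(pu) < 1e-12) return(1e10)
      bc <- numeric(K)
      bc[-drop_i] <- u
      bc[drop_i] <- constant / pu
      -profiled_ll_part(stats, bc)
    }
    for (s in seq_len(n_starts)) {
      start <- if (s == 1L) others else
        others * jitter_factors[(s - 2L) %% length(jitter_factors) + 1L]
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000))
      if (is.finite(opt$value) && opt$value < 1e9 &&
          (is.null(best) || -opt$value > best$pll)) {
        bc <- numeric(K)
        bc[-drop_i] <- opt$par
        bc[drop_i] <- constant / prod(opt$par)
        names(bc) <- stats$cons_eqs
        best <- list(bc = bc, pll = -opt$value)
      }
    }
  }
  if (is.null(best))
    stop("constrained optimization failed to converge from any start")
  best
}

# Assemble a full parameter vector and total log-likelihood from sufficient
# statistics, at constrained-coefficient values bc (NULL = unconstrained).
assemble_fit <- function(model, stats, bc = NULL) {
  n <- stats$n
  beta <- stats::setNames(numeric(nrow(model$coef_table)),
                          model$coef_table$label)
  alpha <- psi <- stats::setNames(numeric(length(model$vars)), model$vars)
  for (v in model$exogenous) {
    alpha[v] <- stats$exo[[v]]$mean
    psi[v] <- stats$exo[[v]]$var
  }
  for (v in names(stats$eqs)) {
    e <- stats$eqs[[v]]
    if (e$type == "free") {
      alpha[v] <- e$coef[1]
      beta[e$labels] <- e$coef[-1]
      psi[v] <- e$rss / n
    } else {
      b <- if (is.null(bc)) e$rxy / e$rxx else bc[[v]]
      other <- e$bz[, 1] - b * e$bz[, 2]
      alpha[v] <- other[1]
      if (length(e$other_labels)) beta[e$other_labels] <- other[-1]
      beta[e$label] <- b
      psi[v] <- rss_quad(e, b) / n
    }
  }
  if (any(psi <= 1e-10))
    warning("fitted variance at or below 1e-10 for: ",
            paste(names(psi)[psi <= 1e-10], collapse = ", "))
  ll <- -n / 2 * sum(log(2 * pi * psi) + 1)
  list(params = list(beta = beta, alpha = alpha, psi = psi),
       log_likelihood = ll)
}

#' Fit the full (unconstrained) path model by maximum likelihood
#'
#' For a recursive model with independent normal residuals the MLE is
#' equation-by-equation least squares with divisor-n residual variances,
#' which is exact; no iteration is involved.  The log-likelihood is that of
#' the joint multivariate normal at the implied moments.
#'
#' @param model a `path_model`
#' @param data data.frame or matrix with columns covering `model$vars`
#' @return object of class `mbco_fit`: `params` (`beta`, `alpha`, `psi`),
#'   `log_likelihood`, `converged`, `constraint_violation` (`NA` for the
#'   full model), `n_obs`, `vcov_beta` (asymptotic covariance of the slope
#'   MLEs from the observed information, block-diagonal across equations),
#'   and `model`.
#' @examples
#' m <- two_mediator_model()
#' d <- simulate_mediation(200, c(b1 = .4, b2 = .4, b3 = .4), seed = 1)
#' fit_full(m, d)
#' @export
fit_full <- function(model, data) {
  Y <- as_model_matrix(model, data)
  stats <- fwl_stats(model, Y, check_rank = TRUE)
  out <- assemble_fit(model, stats)
  structure(list(
    params = out$params,
    log_likelihood = out$log_likelihood,
    converged = TRUE,
    constraint_violation = NA_real_,
    n_obs = stats$n,
    vcov_beta = beta_vcov(model, Y, out$params),
    model = model,
    kind = "full"
  ), class = "mbco_fit")
}

# Observed-information covariance of the slope MLEs: within each equation
# sigma2_ML * (X'X)^{-1}; zero across equations (the joint information is
# block-diagonal over equations for a recursive model).
beta_vcov <- function(model, Y, params) {
  labels <- model$coef_table$label
  V <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (v in names(model$equations)) {
    lab <- model$equations[[v]]
    X <- cbind(1, Y[, names(lab), drop = FALSE])
    Vi <- params$psi[v] * chol2inv(chol(crossprod(X)))
    V[lab, lab] <- Vi[-1, -1, drop = FALSE]
  }
  V
}

#' Fit the null model under the product constraint
#'
#' Maximizes the same likelihood as [fit_full()] subject to the nonlinear
#' equality constraint that the product of the model's tested coefficients
#' equals `constant`.  All parameters other than the constrained
#' coefficients are concentrated out in closed form; for `constant = 0` the
#' constraint set is the exact union of the hyperplanes `b_i = 0` and the
#' optimum is found by enumerating those branches, while for nonzero
#' constants one coefficient is eliminated and the remainder optimized
#' numerically with `n_starts` deterministic starting points.
#'
#' @param model a `path_model` with a `constraint`
#' @param data data.frame or matrix
#' @param constant right-hand side of the constraint; defaults to the
#'   model's declared constant (0 for the usual null of no indirect effect)
#' @param n_starts number of starts for the nonzero-constant search
#' @return an `mbco_fit` (see [fit_full()]); `constraint_violation` is the
#'   absolute departure of the fitted product from `constant`
#' @export
fit_null <- function(model, data, constant = NULL, n_starts = 5) {
  if (is.null(model$constraint))
    stop("model has no constraint; declare one in path_model()")
  if (is.null(constant)) constant <- model$constraint$constant
  Y <- as_model_matrix(model, data)
  stats <- fwl_stats(model, Y, check_rank = TRUE)
  sol <- constrained_profile(stats, constant, n_starts)
  out <- assemble_fit(model, stats, bc = sol$bc)
  full_ll <- assemble_fit(model, stats)$log_likelihood
  if (out$log_likelihood > full_ll + 1e-6)
    stop("internal inconsistency: null log-likelihood exceeds full ",
         "log-likelihood by ", out$log_likelihood - full_ll)
  viol <- abs(prod(out$params$beta[model$constraint$labels]) - constant)
  if (viol > 1e-8)
    stop("constrained fit violates the constraint by ", viol)
  structure(list(
    params = out$params,
    log_likelihood = out$log_likelihood,
    converged = TRUE,
    constraint_violation = viol,
    n_obs = stats$n,
    vcov_beta = NULL,
    model = model,
    kind = "null",
    constant = constant
  ), class = "mbco_fit")
}

#' @export
print.mbco_fit <- function(x, ...) {
  cat("Path model ML fit (", x$kind, " model), n = ", x$n_obs, "\n",
      sep = "")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8), "\n")
  cat("  coefficients:\n")
  print(round(x$params$beta, 4))
  if (!is.na(x$constraint_violation))
    cat("  |g(beta) - c| =", format(x$constraint_violation, digits = 3),
        "\n")
  invisible(x)
}

#' @export
logLik.mbco_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$params$beta) + length(object$params$alpha) +
              length(object$params$psi),
            class = "logLik")
}

#' @export
coef.mbco_fit <- function(object, ...) object$params$beta

# Generic numeric ML optimizer over all free parameters (variances on the
# log scale).  Serves as an independent route to the closed-form MLE; not
# used by the fitting path.
fit_full_numeric <- function(model, data) {
  Y <- as_model_matrix(model, data)
  beta_names <- model$coef_table$label
  nb <- length(beta_names); na <- length(model$vars)
  # moment-based start: slopes 0, intercepts at sample means, variances at
  # sample variances (independent of the closed-form solution)
  th0 <- c(numeric(nb), colMeans(Y)[model$vars],
           log(apply(Y[, model$vars, drop = FALSE], 2, stats::var)))
  unpack <- function(th) list(
    beta = stats::setNames(th[seq_len(nb)], beta_names),
    alpha = stats::setNames(th[nb + seq_len(na)], model$vars),
    psi = stats::setNames(exp(th[(nb + na + 1):length(th)]), model$vars))
  negll <- function(th) -loglik_path(model, unpack(th), Y)
  opt <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt <- stats::optim(opt$par, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(params = unpack(opt$par), log_likelihood = -opt$value,
       converged = opt$convergence == 0)
}
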