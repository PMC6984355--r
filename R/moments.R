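#' Model-implied mean vector and covariance matrix
#'
#' For the recursive system y = a + B y + e with diagonal residual/exogenous
#' covariance Psi, the reduced form gives mu = (I-B)^{-1} a and
#' Sigma = (I-B)^{-1} Psi (I-B)^{-T}.  (I-B) is unit lower-triangular in
#' topological order, hence always invertible for an acyclic model.
#'
#' @param model a `path_model`
#' @param params parameter list with components `beta` (named by coefficient
#'   label), `alpha` (intercepts / exogenous means, named by variable) and
#'   `psi` (residual / exogenous variances, named by variable)
#' @return list with `mean` (named vector) and `cov` (named p x p matrix)
#' @examples
#' m <- two_mediator_model()
#' p <- list(beta = c(b1 = .36, b2 = .36, b3 = .36, b4 = 0, b5 = 0, b6 = 0),
#'           alpha = c(X = 0, M1 = 0, M2 = 0, Y = 0),
#'           psi = c(X = 1, M1 = 1 - .36^2, M2 = 1 - .36^2, Y = 1 - .36^2))
#' implied_moments(m, p)$cov["X", "Y"]   # = 0.36^3
#' @export
implied_moments <- function(model, params) {
  stopifnot(inherits(model, "path_model"))
  check_params(model, params)
  vars <- model$vars
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  for (v in names(model$equations)) {
    lab <- model$equations[[v]]
    B[v, names(lab)] <- params$beta[lab]
  }
  ImB <- diag(p) - B
  # unit triangular in topological order; singularity cannot occur
  A <- solve(ImB)
  mu <- drop(A %*% params$alpha[vars])
  Sigma <- A %*% (params$psi[vars] * t(A))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(vars, vars)
  names(mu) <- vars
  list(mean = mu, cov = Sigma)
}

check_params <- function(model, params) {
  need <- model$coef_table$label
  if (!all(need %in% names(params$beta)))
    stop("params$beta missing: ",
         paste(setdiff(need, names(params$beta)), collapse = ", "))
  if (!all(model$vars %in% names(params$alpha)))
    stop("params$alpha must cover every variable")
  if (!all(model$vars %in% names(params$psi)))
    stop("params$psi must cover every variable")
  if (any(params$psi[model$vars] < 0))
    stop("variances in params$psi must be non-negative")
  invisible(TRUE)
}

#' Joint log-likelihood of raw data under a path model
#'
#' Exact multivariate-normal log-density of the rows at the model-implied
#' moments.  Two algebraically identical routes are available: the joint
#' density at `implied_moments()` (`method = "joint"`) and the sum of
#' per-equation conditional normal densities plus exogenous marginals
#' (`method = "conditional"`, the default, which is cheaper and is what the
#' fitting code maximizes).
#'
#' @param model a `path_model`
#' @param params parameter list as for [implied_moments()]
#' @param data data.frame or matrix with columns covering `model$vars`
#' @param method `"conditional"` or `"joint"`
#' @return scalar log-likelihood
#' @export
loglik_path <- function(model, params, data,
                        method = c("conditional", "joint")) {
  method <- match.arg(method)
  Y <- as_model_matrix(model, data)
  if (method == "joint") {
    mom <- implied_moments(model, params)
    R <- tryCatch(chol(mom$cov),
                  error = function(e) stop("implied covariance is not ",
                                           "positive definite"))
    p <- ncol(Y)
    ctr <- sweep(Y, 2, mom$mean)
    # Sigma = R'R so Sigma^{-1} = R^{-1} R^{-T}; rowwise (y-mu)' R^{-1}
    z <- ctr %*% backsolve(R, diag(p))
    ll <- -0.5 * nrow(Y) * (p * log(2 * pi) + 2 * sum(log(diag(R)))) -
      0.5 * sum(z * z)
    return(ll)
  }
  ll <- 0
  for (v in model$exogenous) {
    ll <- ll + sum(stats::dnorm(Y[, v], params$alpha[v],
                                sqrt(params$psi[v]), log = TRUE))
  }
  for (v in names(model$equations)) {
    lab <- model$equations[[v]]
    fitted <- params$alpha[v] +
      Y[, names(lab), drop = FALSE] %*% params$beta[lab]
    ll <- ll + sum(stats::dnorm(Y[, v], drop(fitted),
                                sqrt(params$psi[v]), log = TRUE))
  }
  unname(ll)
}

# validated numeric matrix with the model's columns, topological order
as_model_matrix <- function(model, data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  missing <- setdiff(model$vars, colnames(data))
  if (length(missing))
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  Y <- data[, model$vars, drop = FALSE]
  if (anyNA(Y)) stop("missing values are not supported")
  Y
}
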