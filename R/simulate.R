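#' Simulate data from a recursive path model
#'
#' Generates `n` rows from the model's structural equations in topological
#' order.  Coefficients absent from `betas` default to zero; intercepts are
#' zero.  Two variance conventions are available:
#' \describe{
#'   \item{`"unit_residual"` (default)}{every exogenous variable and every
#'     residual has variance 1.  This is the convention of the classical
#'     mediation power tables from which the study's effect sizes are
#'     taken: 0.14 "small", 0.39 "medium", 0.59 "large" correspond to
#'     Cohen's R-squared guidelines of about 0.02, 0.13, 0.26 (on the
#'     correlation metric those coefficients are roughly 0.14, 0.36, and
#'     0.5).}
#'   \item{`"standardized"`}{every exogenous variable has variance 1 and
#'     each endogenous residual variance is set so the total variance is 1,
#'     putting coefficients on the correlation scale; coefficient
#'     configurations whose explained variance reaches 1 are rejected.}
#' }
#'
#' Under `distribution = "nonnormal"` the exogenous variables and every
#' residual are drawn by the Fleishman power method at the given marginal
#' skewness and excess kurtosis (the Vale-Maurelli construction; the
#' residuals are mutually independent, so univariate transforms suffice),
#' then scaled to the required variance — scaling preserves the
#' standardized moments.
#'
#' @param n sample size (at least 10)
#' @param betas named numeric vector of coefficient values, e.g.
#'   `c(b1 = .36, b2 = .36, b3 = .36)`; unnamed scalar is an error
#' @param model a `path_model`; defaults to [two_mediator_model()]
#' @param distribution `"normal"` or `"nonnormal"`
#' @param skewness,kurtosis marginal targets for the non-normal case
#'   (kurtosis is excess); the study's moderate condition is (2, 7) and the
#'   severe condition (3, 21)
#' @param scale `"unit_residual"` or `"standardized"` (see Details)
#' @param seed optional integer seed
#' @return data.frame with `n` rows and the model's variables as columns
#' @examples
#' d <- simulate_mediation(500, c(b1 = .36, b2 = .36, b3 = .36),
#'                         scale = "standardized", seed = 1)
#' round(cor(d)["X", "M1"], 2)
#' @export
simulate_mediation <- function(n, betas, model = two_mediator_model(),
                               distribution = c("normal", "nonnormal"),
                               skewness = 0, kurtosis = 0,
                               scale = c("unit_residual", "standardized"),
                               seed = NULL) {
  distribution <- match.arg(distribution)
  scale <- match.arg(scale)
  if (n < 10) stop("n must be at least 10")
  if (is.null(names(betas)) && length(betas) > 0)
    stop("betas must be a named vector of coefficient values")
  unknown <- setdiff(names(betas), model$coef_table$label)
  if (length(unknown))
    stop("unknown coefficient(s) in betas: ",
         paste(unknown, collapse = ", "))
  beta <- stats::setNames(numeric(nrow(model$coef_table)),
                          model$coef_table$label)
  beta[names(betas)] <- betas
  psi <- if (scale == "standardized") standardized_psi(model, beta) else
    stats::setNames(rep(1, length(model$vars)), model$vars)
  if (!is.null(seed)) set.seed(seed)
  fl <- if (distribution == "nonnormal")
    fleishman_coefficients(skewness, kurtosis)
  draw <- function(m) {
    if (distribution == "normal") stats::rnorm(m) else
      rfleishman(m, coef = fl)
  }
  Y <- matrix(0, n, length(model$vars),
              dimnames = list(NULL, model$vars))
  for (v in model$vars) {
    if (v %in% model$exogenous) {
      Y[, v] <- sqrt(psi[v]) * draw(n)
    } else {
      lab <- model$equations[[v]]
      Y[, v] <- Y[, names(lab), drop = FALSE] %*% beta[lab] +
        sqrt(psi[v]) * draw(n)
    }
  }
  as.data.frame(Y)
}

# Residual/exogenous variances giving every variable unit implied variance.
# Walk the topological order keeping the implied covariance of the
# processed variables; the residual variance of each endogenous variable is
# 1 minus its explained variance.
standardized_psi <- function(model, beta) {
  vars <- model$vars
  psi <- stats::setNames(numeric(length(vars)), vars)
  Sigma <- matrix(0, 0, 0)
  done <- character(0)
  for (v in vars) {
    if (v %in% model$exogenous) {
      psi[v] <- 1
      newcov <- rep(0, length(done))
    } else {
      lab <- model$equations[[v]]
      b <- beta[lab]
      Spp <- Sigma[names(lab), names(lab), drop = FALSE]
      explained <- drop(t(b) %*% Spp %*% b)
      psi[v] <- 1 - explained
      if (psi[v] <= 0)
        stop("coefficients too large to standardize: explained variance ",
             "of ", v, " is ", round(explained, 4), " >= 1")
      newcov <- drop(Sigma[done, names(lab), drop = FALSE] %*% b)
    }
    Sigma <- rbind(cbind(Sigma, newcov), c(newcov, 1))
    done <- c(done, v)
    dimnames(Sigma) <- list(done, done)
  }
  psi
}
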