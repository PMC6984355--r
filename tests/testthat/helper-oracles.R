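# Independent oracles used across the test files.  These deliberately go
# through lm()/dnorm() rather than the package's own fitting path.

# conditional ML log-likelihood of one lm equation (divisor-n variance)
ll_lm <- function(formula, data) {
  fit <- lm(formula, data = data)
  n <- nrow(data)
  s2 <- sum(resid(fit)^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

# marginal ML log-likelihood of an exogenous column
ll_exo <- function(x) {
  n <- length(x)
  s2 <- sum((x - mean(x))^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

# full-model log-likelihood of the covariate-free two-mediator model
oracle_full_ll <- function(d) {
  ll_lm(M1 ~ X, d) + ll_lm(M2 ~ M1 + X, d) + ll_lm(Y ~ M2 + M1 + X, d) +
    ll_exo(d$X)
}

# null-model log-likelihood: best of the three zero-coefficient branches
oracle_null_ll <- function(d) {
  max(ll_lm(M1 ~ 1, d) + ll_lm(M2 ~ M1 + X, d) + ll_lm(Y ~ M2 + M1 + X, d),
      ll_lm(M1 ~ X, d) + ll_lm(M2 ~ X, d) + ll_lm(Y ~ M2 + M1 + X, d),
      ll_lm(M1 ~ X, d) + ll_lm(M2 ~ M1 + X, d) + ll_lm(Y ~ M1 + X, d)) +
    ll_exo(d$X)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / (mean((x - m)^2))^2 - 3
}

# standard parameter list for the covariate-free two-mediator model
chain_params <- function(b, psi = 1 - b^2) {
  list(beta = c(b1 = b, b2 = b, b3 = b, b4 = 0, b5 = 0, b6 = 0),
       alpha = c(X = 0, M1 = 0, M2 = 0, Y = 0),
       psi = c(X = 1, M1 = psi, M2 = psi, Y = psi))
}
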