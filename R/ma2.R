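#' MA(2) residual covariance over measurement occasions
#'
#' Covariance matrix of an order-2 moving-average process indexed by
#' consecutive within-fish measurement occasions (ARMA(0,2)), normalised so
#' that `sigma^2` is the marginal residual variance: with
#' s = 1 / (1 + theta1^2 + theta2^2),
#' lag-0 = sigma^2, lag-1 = sigma^2 s (theta1 + theta1 theta2),
#' lag-2 = sigma^2 s theta2, zero beyond lag 2. Occasions are positional:
#' the calendar gap between measurements (14 d for females, 21 d for males)
#' does not enter.
#'
#' @param sigma Marginal residual SD (mm), > 0.
#' @param theta1,theta2 MA coefficients (any real).
#' @param n_obs Number of occasions, >= 1.
#' @return `n_obs` x `n_obs` banded Toeplitz covariance matrix.
#' @export
ma2_covariance <- function(sigma, theta1, theta2, n_obs) {
  stopifnot(sigma > 0, n_obs >= 1)
  s <- 1 / (1 + theta1^2 + theta2^2)
  g <- c(sigma^2,
         sigma^2 * s * (theta1 + theta1 * theta2),
         sigma^2 * s * theta2)
  V <- matrix(0, n_obs, n_obs)
  for (lag in 0:min(2, n_obs - 1)) {
    idx <- seq_len(n_obs - lag)
    V[cbind(idx, idx + lag)] <- g[lag + 1]
    V[cbind(idx + lag, idx)] <- g[lag + 1]
  }
  V
}

#' Simulate MA(2) residual vectors
#'
#' Draws residual series with the covariance of [ma2_covariance()] by
#' filtering iid innovations: e_t = (z_t + theta1 z_{t-1} + theta2 z_{t-2})
#' scaled so the marginal SD is `sigma`.
#'
#' @inheritParams ma2_covariance
#' @param n_series Number of independent series.
#' @return `n_series` x `n_obs` matrix.
#' @export
simulate_ma2 <- function(sigma, theta1, theta2, n_obs, n_series) {
  z <- matrix(stats::rnorm((n_obs + 2) * n_series), n_series, n_obs + 2)
  scale <- sigma / sqrt(1 + theta1^2 + theta2^2)
  e <- z[, 3:(n_obs + 2), drop = FALSE] +
    theta1 * z[, 2:(n_obs + 1), drop = FALSE] +
    theta2 * z[, 1:n_obs, drop = FALSE]
  e * scale
}
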