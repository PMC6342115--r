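#' Matern hyperparameters (smoothness 1)
#'
#' The field is parameterised by its marginal variance `sigma2` and its
#' spatial `range`, the distance at which correlation has dropped to roughly
#' 0.1. Smoothness is fixed at nu = 1 (the SPDE alpha = 2 case on a
#' two-dimensional domain). The SPDE scale parameters are derived as
#' `kappa = sqrt(8 * nu) / range` and `tau = 1 / (sqrt(4 * pi) * kappa *
#' sigma)`, from the stationary identity `sigma2 = 1 / (4 * pi * kappa^2 *
#' tau^2)`; the two parameterisations are bijective.
#'
#' @param sigma2 Marginal variance (> 0), in squared mark-scale units.
#' @param range Correlation range (> 0), in the grid's length units.
#' @return An object of class `matern_hyper` with fields `sigma2`, `range`,
#'   `nu`, `kappa`, `tau`.
#' @examples
#' h <- matern_hyper(sigma2 = 1, range = 20)
#' matern_correlation(20, h)  # about 0.14
#' @export
matern_hyper <- function(sigma2 = 1, range) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("sigma2 must be a positive finite scalar")
  if (!is.numeric(range) || length(range) != 1L || !is.finite(range) ||
      range <= 0)
    stop("range must be a positive finite scalar")
  nu <- 1
  kappa <- sqrt(8 * nu) / range
  tau <- 1 / (sqrt(4 * pi) * kappa * sqrt(sigma2))
  structure(list(sigma2 = as.numeric(sigma2), range = as.numeric(range),
                 nu = nu, kappa = kappa, tau = tau),
            class = "matern_hyper")
}

#' @export
print.matern_hyper <- function(x, ...) {
  cat(sprintf(
    "<matern_hyper> nu=1, sigma2=%g, range=%g (kappa=%g, tau=%g)\n",
    x$sigma2, x$range, x$kappa, x$tau))
  invisible(x)
}

#' Recover (sigma2, range) from the SPDE scales
#'
#' Inverse of the derivation in [matern_hyper()]: round-trips to machine
#' precision.
#'
#' @param kappa,tau SPDE scale parameters (> 0).
#' @return A `matern_hyper`.
#' @export
matern_hyper_from_spde <- function(kappa, tau) {
  if (any(c(kappa, tau) <= 0) || any(!is.finite(c(kappa, tau))))
    stop("kappa and tau must be positive and finite")
  sigma2 <- 1 / (4 * pi * kappa^2 * tau^2)
  matern_hyper(sigma2 = sigma2, range = sqrt(8) / kappa)
}

#' Matern correlation function (nu = 1)
#'
#' Evaluates `rho(d) = kappa * d * K_1(kappa * d)` with the exponentially
#' scaled Bessel function for numerical stability at large lags; `rho(0) = 1`
#' by continuity and the function decreases strictly with distance.
#'
#' @param distance Non-negative distances (grid length units).
#' @param hyper A `matern_hyper`.
#' @return Correlations in `[0, 1]`, same length as `distance`.
#' @export
matern_correlation <- function(distance, hyper) {
  stopifnot(inherits(hyper, "matern_hyper"))
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and non-negative")
  x <- hyper$kappa * distance
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- 1
  xb <- x[!small]
  out[!small] <- xb * besselK(xb, nu = 1, expon.scaled = TRUE) * exp(-xb)
  out
}

#' Dense Matern covariance matrix
#'
#' Covariance between all pairs of the supplied points; used by the exact
#' (dense Cholesky) simulation path and by small-grid oracles.
#'
#' @param coords Two-column coordinate matrix.
#' @param hyper A `matern_hyper`.
#' @return A dense symmetric covariance matrix.
#' @export
matern_covariance <- function(coords, hyper) {
  stopifnot(inherits(hyper, "matern_hyper"))
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  rho <- matern_correlation(as.numeric(d), hyper)
  matrix(hyper$sigma2 * rho, nrow = nrow(coords))
}
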