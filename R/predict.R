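#' Lognormal-corrected predictive mean
#'
#' For log-link families the posterior predictive mean of the abundance
#' `mu = exp(eta)` under a Gaussian latent approximation `eta ~ N(m, v)` is
#' `E[exp(eta)] = exp(m + v/2)`, not `exp(m)`; at `v = 0` the two coincide.
#' For identity-link (gaussian) marks the predictive mean is `m` itself.
#'
#' @param m Posterior mean of the linear predictor, per cell.
#' @param v Posterior variance of the linear predictor (>= 0), per cell.
#' @param family Mark family.
#' @return List with `mean` and `sd` of the predictive abundance scale.
#' @export
predictive_mean <- function(m, v, family = c("gamma", "gaussian",
                                             "lognormal", "poisson")) {
  family <- match.arg(family)
  if (any(v < 0)) stop("latent variances must be non-negative")
  if (family == "gaussian")
    return(list(mean = m, sd = sqrt(v)))
  mu <- exp(m + v / 2)
  list(mean = mu, sd = mu * sqrt(pmax(exp(v) - 1, 0)))
}

#' Posterior predictive abundance surface
#'
#' Evaluates, for every cell of the study window, the posterior mean and
#' standard deviation of the abundance level `mu_s` implied by the Gaussian
#' approximation of the latent field at the hyperparameter mode. For
#' log-link families the mean carries the lognormal correction
#' `exp(m + v/2)` (see [predictive_mean()]), so all predicted means are
#' strictly positive.
#'
#' @param fit A converged `psdm_fit`.
#' @param grid Optional grid; must equal the fit's study window.
#' @return List of class `psdm_prediction` with `mean` and `sd`
#'   (`latent_field`s) and the per-cell latent `m` and `v`.
#' @export
predict_surface <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "psdm_fit"))
  if (!isTRUE(fit$converged)) stop("cannot predict from an unconverged fit")
  frame <- fit$frame
  if (!is.null(grid) &&
      !(grid$nx == frame$grid$nx && grid$ny == frame$grid$ny &&
          grid$cell_size == frame$grid$cell_size))
    stop("prediction grid does not match the fitted grid")
  # linear predictor of each window cell: w + beta_mark (+ smooth)
  ii <- c(frame$window, rep(frame$idx_bm, frame$N_win))
  jj <- c(seq_len(frame$N_win), seq_len(frame$N_win))
  if (!is.null(frame$smooth)) {
    ii <- c(ii, frame$idx_f[frame$smooth$bin_cell])
    jj <- c(jj, seq_len(frame$N_win))
  }
  Ap <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                             dims = c(frame$p, frame$N_win))
  m <- as.numeric(Matrix::crossprod(Ap, fit$latent_mode))
  y1 <- Matrix::solve(fit$chol, Ap, system = "P")
  y2 <- Matrix::solve(fit$chol, y1, system = "L")
  v <- as.numeric(Matrix::colSums(y2^2))
  pm <- predictive_mean(m, v, fit$spec$mark_family)
  structure(list(mean = latent_field(frame$grid, pm$mean),
                 sd = latent_field(frame$grid, pm$sd),
                 m = m, v = v, family = fit$spec$mark_family),
            class = "psdm_prediction")
}

#' @export
print.psdm_prediction <- function(x, ...) {
  cat(sprintf("<psdm_prediction> %s-family surface on %d x %d grid\n",
              x$family, x$mean$grid$nx, x$mean$grid$ny))
  invisible(x)
}
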