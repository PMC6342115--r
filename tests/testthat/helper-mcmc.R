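# Independent MCMC oracle for the Laplace fitter.
#
# Targets the SAME unnormalised posterior as the package's preferential
# gamma model (marks + lattice Poisson counts + GMRF field + intercepts +
# hyperpriors) with entirely its own dense-matrix code: the lattice
# precision is rebuilt from Kronecker products here, densities and
# derivatives are written out directly, and the latent mode/curvature used
# below is found by a dense Newton iteration. The sampler is exact
# Metropolis-Hastings:
#
#   (1) latent refresh: independence MH with a N(mode, H^-1) proposal from
#       the oracle's own dense Laplace approximation at the current
#       hyperparameters (the proposal only affects efficiency; the accept
#       ratio corrects it exactly);
#   (2) joint hyperparameter move: random-walk proposal on
#       (2 log kappa, log tau, log rho, alpha) with the latent vector
#       simultaneously redrawn from the Laplace proposal at the proposed
#       hyperparameters, accepted with the exact joint ratio. This mixes
#       the hyperparameters against their (approximate) marginal rather
#       than their full conditional, avoiding the variance funnel.
#
# Every density evaluation is independent of the package's engine, so the
# oracle checks the whole Laplace/Newton/optimisation path.

mcmc_oracle <- function(data, grid, extension, n_iter = 20000,
                        burn = 2000, seed = 99, prior_spread = c(3, 3)) {
  set.seed(seed)
  y <- data$data$mark
  cells <- data$data$cell
  counts <- tabulate(cells, nbins = n_cells(grid))
  area <- grid$cell_size^2
  ext <- extend_grid(grid, extension)
  N <- n_cells(ext$grid)
  p <- N + 2L
  win <- ext$window
  wobs <- win[cells]
  n <- length(y)

  # lattice SPDE precision, built independently from Kronecker products
  lap1 <- function(nn) {
    L <- diag(c(1, rep(2, nn - 2), 1))
    L[cbind(1:(nn - 1), 2:nn)] <- -1
    L[cbind(2:nn, 1:(nn - 1))] <- -1
    L
  }
  Gx <- lap1(ext$grid$nx); Gy <- lap1(ext$grid$ny)
  G <- kronecker(diag(ext$grid$ny), Gx) + kronecker(Gy, diag(ext$grid$nx))
  G2 <- G %*% G
  h <- ext$grid$cell_size
  Qfun <- function(th) {
    kap <- exp(th[1] / 2); tau <- exp(th[2])
    tau^2 * (kap^4 * h^2 * diag(N) + 2 * kap^2 * G + G2 / h^2)
  }

  # observation matrices: eta = A u (marks), v = B(alpha) u (cells)
  A <- matrix(0, n, p)
  A[cbind(seq_len(n), wobs)] <- 1
  A[, N + 1L] <- 1
  Bw <- matrix(0, length(win), p)
  Bw[cbind(seq_along(win), win)] <- 1
  Bcol <- N + 2L

  mh0 <- matern_hyper(1, 0.5 * max(grid$nx, grid$ny) * grid$cell_size)
  hyperprior <- function(th)
    dnorm(th[1], 2 * log(mh0$kappa), prior_spread[1], log = TRUE) +
    dnorm(th[2], log(mh0$tau), prior_spread[2], log = TRUE) +
    dnorm(th[3], 0, 10, log = TRUE) +
    dnorm(th[4], 0, 1, log = TRUE)

  # log joint (up to a constant), gradient and Hessian in u
  make_cache <- function(th) {
    Q <- Qfun(th)
    cQ <- chol(Q)
    list(th = th, Q = Q,
         logdetQ = 2 * sum(log(diag(cQ))),
         rho = exp(th[3]), alpha = th[4])
  }
  logjoint <- function(u, ca) {
    w <- u[1:N]; bm <- u[N + 1]; bp <- u[N + 2]
    eta <- bm + w[wobs]
    v <- bp + ca$alpha * w[win]
    sum(dgamma(y, shape = ca$rho, rate = ca$rho / exp(eta), log = TRUE)) +
      sum(dpois(counts, area * exp(v), log = TRUE)) +
      0.5 * ca$logdetQ - 0.5 * sum(w * (ca$Q %*% w)) -
      (bm^2 + bp^2) / 200 +
      hyperprior(ca$th)
  }
  grad_hess <- function(u, ca) {
    w <- u[1:N]; bm <- u[N + 1]; bp <- u[N + 2]
    eta <- bm + w[wobs]
    v <- bp + ca$alpha * w[win]
    # gamma: d/deta logdens = rho (y e^-eta - 1); d2 = -rho y e^-eta
    g1 <- ca$rho * (y * exp(-eta) - 1)
    g2 <- ca$rho * y * exp(-eta)
    lam <- area * exp(v)
    p1 <- counts - lam
    B <- ca$alpha * Bw
    B[, Bcol] <- 1
    g <- as.numeric(crossprod(A, g1)) + as.numeric(crossprod(B, p1))
    g[1:N] <- g[1:N] - as.numeric(ca$Q %*% w)
    g[N + 1] <- g[N + 1] - bm / 100
    g[N + 2] <- g[N + 2] - bp / 100
    H <- -crossprod(A, g2 * A) - crossprod(B, lam * B)
    H[1:N, 1:N] <- H[1:N, 1:N] - ca$Q
    H[N + 1, N + 1] <- H[N + 1, N + 1] - 1 / 100
    H[N + 2, N + 2] <- H[N + 2, N + 2] - 1 / 100
    list(g = g, H = H)
  }
  # dense Newton for the oracle's own Laplace proposal at th
  laplace_at <- function(ca, u0) {
    u <- u0
    for (it in 1:50) {
      gh <- grad_hess(u, ca)
      if (max(abs(gh$g)) < 1e-9) break
      P <- -gh$H
      cP <- chol(P)
      step <- backsolve(cP, forwardsolve(t(cP), gh$g))
      t_ <- 1
      f0 <- logjoint(u, ca)
      repeat {
        u2 <- u + t_ * step
        if (is.finite(logjoint(u2, ca)) && logjoint(u2, ca) >= f0 - 1e-12)
          break
        t_ <- t_ / 2
        if (t_ < 1e-10) { u2 <- u; break }
      }
      u <- u2
    }
    gh <- grad_hess(u, ca)
    cP <- chol(-gh$H)
    list(mode = u, cP = cP, logdetP = 2 * sum(log(diag(cP))))
  }
  draw_prop <- function(lap) {
    z <- rnorm(p)
    as.numeric(lap$mode + backsolve(lap$cP, z))
  }
  dprop <- function(u, lap) {
    r <- as.numeric(lap$cP %*% (u - lap$mode))
    0.5 * lap$logdetP - 0.5 * sum(r^2)
  }

  th <- c(2 * log(mh0$kappa), log(mh0$tau), log(5), 0.5)
  ca <- make_cache(th)
  u0 <- c(numeric(N), log(mean(y)), log(n / (n_cells(grid) * area)))
  lap <- laplace_at(ca, u0)
  u <- lap$mode
  scale <- 0.5
  prop_chol <- diag(0.3, 4)
  acc_u <- acc_t <- tries_t <- 0L
  th_hist <- matrix(NA_real_, n_iter, 4)
  wsum <- numeric(length(win))
  th_draws <- matrix(NA_real_, n_iter - burn, 4)
  k <- 0L
  for (it in seq_len(n_iter)) {
    # (1) latent refresh
    up <- draw_prop(lap)
    logr <- logjoint(up, ca) - logjoint(u, ca) -
      dprop(up, lap) + dprop(u, lap)
    if (is.finite(logr) && log(runif(1)) < logr) {
      u <- up; acc_u <- acc_u + 1L
    }
    # (2) joint hyperparameter + latent move (adaptive covariance)
    thp <- th + scale * as.numeric(prop_chol %*% rnorm(4))
    tries_t <- tries_t + 1L
    cap <- tryCatch(make_cache(thp), error = function(e) NULL)
    if (!is.null(cap)) {
      lapp <- tryCatch(laplace_at(cap, u), error = function(e) NULL)
      if (!is.null(lapp)) {
        upp <- draw_prop(lapp)
        logr <- logjoint(upp, cap) - logjoint(u, ca) -
          dprop(upp, lapp) + dprop(u, lap)
        if (is.finite(logr) && log(runif(1)) < logr) {
          th <- thp; ca <- cap; lap <- lapp; u <- upp
          acc_t <- acc_t + 1L
        }
      }
    }
    th_hist[it, ] <- th
    if (it <= burn && it %% 100 == 0) {
      scale <- min(max(scale * exp(acc_t / tries_t - 0.25), 0.05), 3)
      acc_t <- tries_t <- 0L
      if (it >= burn / 2) {
        cv <- stats::cov(th_hist[(it %/% 2):it, ]) + diag(1e-4, 4)
        prop_chol <- t(chol(cv)) * (2.38 / 2)
        scale <- 1
      }
    }
    if (it > burn) {
      k <- k + 1L
      wsum <- wsum + u[win]
      th_draws[k, ] <- th
    }
  }
  list(latent_mean = wsum / k, theta = th_draws[seq_len(k), , drop = FALSE],
       accept_latent = acc_u / n_iter)
}
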