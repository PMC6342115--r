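#' Prior specification
#'
#' Priors for the latent Gaussian model. Fixed effects (the two intercepts)
#' get independent zero-mean Gaussians with variance `fixed_variance`
#' (default 100). The Matern hyperparameters, optimised on the unconstrained
#' scale `(2 log kappa, log tau)`, take one of two prior styles:
#'
#' * `"median"` (default): independent Gaussians centred so that the prior
#'   median range is `range0` (default half the study-window width) and the
#'   prior median marginal standard deviation is `sigma0` (default 1), with
#'   generous spreads `spread` on the unconstrained scale;
#' * `"pc"`: penalised-complexity priors, specified through the tail
#'   probabilities `P(range < pc_range[1]) = pc_range[2]` and
#'   `P(sd > pc_sigma[1]) = pc_sigma[2]`.
#'
#' The gamma dispersion `rho` (and the gaussian noise precision) get a vague
#' Gaussian on the log scale; the sharing scales `alpha`, `alpha_d` get
#' standard normal priors on the natural scale; the RW2 log-precision gets
#' a LogGamma(4, 0.0001) prior (i.e. `rho_d ~ Gamma(4, 0.0001)`).
#'
#' @param fixed_variance Gaussian prior variance of the intercepts.
#' @param spatial_style `"median"` or `"pc"`.
#' @param range0,sigma0 Prior-median range and field sd for the `"median"`
#'   style (`range0 = NULL` means half the window width, resolved at fit
#'   time).
#' @param spread Length-2 positive sds of the `"median"`-style Gaussians on
#'   `(2 log kappa, log tau)`.
#' @param pc_range Length-2 `(r0, p_r)` for the `"pc"` style.
#' @param pc_sigma Length-2 `(s0, p_s)` for the `"pc"` style.
#' @param alpha_sd Prior sd of the sharing scales (default 1).
#' @param rho_d_prior Length-2 (shape, rate) of the RW2 precision Gamma
#'   prior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_variance = 100,
                       spatial_style = c("median", "pc"),
                       range0 = NULL, sigma0 = 1, spread = c(3, 3),
                       pc_range = c(NA, 0.25), pc_sigma = c(2, 0.1),
                       alpha_sd = 1, rho_d_prior = c(4, 1e-4)) {
  spatial_style <- match.arg(spatial_style)
  stopifnot(fixed_variance > 0, length(spread) == 2, all(spread > 0),
            length(pc_range) == 2, length(pc_sigma) == 2,
            alpha_sd > 0, length(rho_d_prior) == 2, all(rho_d_prior > 0))
  structure(list(fixed_variance = fixed_variance,
                 spatial_style = spatial_style,
                 range0 = range0, sigma0 = sigma0, spread = spread,
                 pc_range = pc_range, pc_sigma = pc_sigma,
                 alpha_sd = alpha_sd, rho_d_prior = rho_d_prior),
            class = "prior_spec")
}

#' Model specification
#'
#' Declares which model to fit. The preferential model couples the mark
#' likelihood to a log-Gaussian Cox process over the sampling locations,
#' sharing the latent Matern field (scaled by `alpha`, estimated) and
#' optionally a covariate smooth (scaled by `alpha_d`); the non-preferential
#' baseline is the mark-only geostatistical model with its own independent
#' field.
#'
#' @param mark_family `"gamma"` (default), `"gaussian"`, `"lognormal"` or
#'   `"poisson"`.
#' @param preferential Logical; include the point-process layer with a
#'   shared field.
#' @param share_spatial Logical; share the spatial field into the
#'   point-process predictor (scaled by `alpha`). A preferential model must
#'   share at least one component.
#' @param share_covariate Logical; also share the covariate smooth into the
#'   point-process predictor (scaled by `alpha_d`). Experimental: when the
#'   smooth and the field carry the same information the point-process
#'   layer is confounded, which the fitter detects and reports.
#' @param covariate_smooth `NULL`, or a list with `nbins` (number of RW2
#'   knots over the covariate, default 20) requesting a second-order
#'   random-walk smooth of the covariate in the mark predictor.
#' @param priors A [prior_spec()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(mark_family = c("gamma", "gaussian", "lognormal",
                                       "poisson"),
                       preferential = TRUE, share_spatial = TRUE,
                       share_covariate = FALSE, covariate_smooth = NULL,
                       priors = prior_spec()) {
  mark_family <- match.arg(mark_family)
  stopifnot(inherits(priors, "prior_spec"))
  if (preferential && !share_spatial && !share_covariate)
    stop("a preferential model must share at least one component")
  if (!preferential) {
    share_spatial <- FALSE
    share_covariate <- FALSE
  }
  if (share_covariate && is.null(covariate_smooth))
    stop("share_covariate requires a covariate_smooth")
  if (!is.null(covariate_smooth)) {
    if (is.null(covariate_smooth$nbins)) covariate_smooth$nbins <- 20L
    if (covariate_smooth$nbins < 3L) stop("covariate smooth needs >= 3 bins")
  }
  structure(list(mark_family = mark_family,
                 preferential = isTRUE(preferential),
                 share_spatial = isTRUE(share_spatial),
                 share_covariate = isTRUE(share_covariate),
                 covariate_smooth = covariate_smooth,
                 priors = priors),
            class = "model_spec")
}

#' Bin a point pattern onto the grid
#'
#' The lattice approximation of the log-Gaussian Cox process likelihood:
#' cell counts are conditionally Poisson with mean `exposure * intensity`,
#' where the exposure of every in-window cell is its area.
#'
#' @param locations Data frame with a `cell` column, or `x`/`y` columns.
#' @param grid A `grid_geometry`.
#' @return List with integer `counts` and numeric `exposure`, one entry per
#'   grid cell.
#' @export
bin_point_pattern <- function(locations, grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  if (!is.null(locations$cell)) cells <- as.integer(locations$cell)
  else cells <- cell_index(grid, locations$x, locations$y)
  if (length(cells) && (any(cells < 1L) || any(cells > n_cells(grid))))
    stop("location outside the grid window")
  counts <- tabulate(cells, nbins = n_cells(grid))
  list(counts = as.integer(counts),
       exposure = rep(grid$cell_size^2, n_cells(grid)))
}

# ---- mark families -------------------------------------------------------

# negative log density of the marks and its first two derivatives w.r.t.
# the linear predictor eta
.family_nll <- function(family, y, eta, par) {
  switch(family,
    gamma = {
      rho <- par$rho
      e <- exp(-eta)
      list(nll = -(rho * (log(rho) - eta) + (rho - 1) * log(y) -
                     rho * y * e - lgamma(rho)),
           d1 = rho - rho * y * e,
           d2 = rho * y * e)
    },
    gaussian = {
      prec <- par$prec_e
      r <- y - eta
      list(nll = 0.5 * log(2 * pi / prec) + 0.5 * prec * r^2,
           d1 = -prec * r,
           d2 = rep(prec, length(y)))
    },
    lognormal = {
      prec <- par$prec_e
      ly <- log(y)
      r <- ly - eta
      list(nll = 0.5 * log(2 * pi / prec) + 0.5 * prec * r^2 + ly,
           d1 = -prec * r,
           d2 = rep(prec, length(y)))
    },
    poisson = {
      mu <- exp(eta)
      list(nll = mu - y * eta + lgamma(y + 1),
           d1 = mu - y,
           d2 = mu)
    },
    stop("unknown mark family: ", family))
}

# log predictive density of a single mark given eta (vectorised over eta)
.family_logdens <- function(family, y, eta, par) {
  -.family_nll(family, y, eta, par)$nll
}

# ---- model frame ---------------------------------------------------------

# Assembles everything that does not depend on the hyperparameters:
# incidence matrices, binned counts, the SPDE lattice structure and its
# Laplacian eigenvalues (for O(N) log-determinants), the scaled RW2 penalty.
.build_frame <- function(spec, data, grid = NULL, covariate = NULL,
                         extension = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "marked_sample"))
  if (is.null(grid)) grid <- data$grid
  if (is.null(grid)) stop("a grid_geometry is required")
  y <- data$data$mark
  if (length(y) < 1L) stop("the marked sample is empty")
  if (spec$mark_family %in% c("gamma", "lognormal") && any(y <= 0))
    stop(sprintf("%s marks must be strictly positive", spec$mark_family))
  cells <- data$data$cell
  if (is.null(cells)) cells <- cell_index(grid, data$data$x, data$data$y)
  if (any(cells < 1L | cells > n_cells(grid)))
    stop("sample location outside the grid")

  if (is.null(extension))
    extension <- ceiling(0.2 * max(grid$nx, grid$ny))
  ext <- extend_grid(grid, extension)
  N_ext <- n_cells(ext$grid)
  N_win <- n_cells(grid)

  # smooth setup
  smooth <- NULL
  if (!is.null(spec$covariate_smooth)) {
    if (is.null(covariate))
      stop("a covariate surface is required for a covariate smooth")
    stopifnot(inherits(covariate, "latent_field"))
    covv <- covariate$values
    nb <- spec$covariate_smooth$nbins
    brk <- seq(min(covv), max(covv), length.out = nb + 1L)
    bin_of <- function(v) pmin(pmax(findInterval(v, brk,
                                                 rightmost.closed = TRUE),
                                    1L), nb)
    knots <- (brk[-1] + brk[-length(brk)]) / 2
    Rf <- build_rw2_precision(nb)
    smooth <- list(m = nb, knots = knots, Rf = Rf,
                   Rf_eig = eigen(as.matrix(Rf), symmetric = TRUE,
                                  only.values = TRUE)$values,
                   bin_obs = bin_of(covv[cells]),
                   bin_cell = bin_of(covv),
                   eps = 1e-6)
  }
  m_f <- if (is.null(smooth)) 0L else smooth$m

  # latent layout: [w_ext, f, beta_mark, beta_pp]
  idx_w <- seq_len(N_ext)
  idx_f <- if (m_f) N_ext + seq_len(m_f) else integer(0)
  idx_bm <- N_ext + m_f + 1L
  idx_bp <- if (spec$preferential) idx_bm + 1L else integer(0)
  p <- idx_bm + as.integer(spec$preferential)

  n <- length(y)
  ii <- c(seq_len(n), seq_len(n))
  jj <- c(ext$window[cells], rep(idx_bm, n))
  if (m_f) {
    ii <- c(ii, seq_len(n))
    jj <- c(jj, idx_f[smooth$bin_obs])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, p))

  pp <- NULL
  if (spec$preferential) {
    binned <- bin_point_pattern(data.frame(cell = cells), grid)
    kk <- seq_len(N_win)
    Bw <- Matrix::sparseMatrix(i = kk, j = ext$window, x = 1,
                               dims = c(N_win, p))
    B0 <- Matrix::sparseMatrix(i = kk, j = rep(idx_bp, N_win), x = 1,
                               dims = c(N_win, p))
    Bf <- if (spec$share_covariate)
      Matrix::sparseMatrix(i = kk, j = idx_f[smooth$bin_cell], x = 1,
                           dims = c(N_win, p))
    else NULL
    pp <- list(counts = binned$counts, exposure = binned$exposure,
               Bw = Bw, B0 = B0, Bf = Bf)
  }

  st <- .spde_structure(ext$grid)
  # Laplacian eigenvalues of the extended lattice, for closed-form logdet Q
  lam1 <- function(nn) 2 - 2 * cos(pi * (0:(nn - 1)) / nn)
  lam <- as.numeric(outer(lam1(ext$grid$nx), lam1(ext$grid$ny), "+"))

  list(spec = spec, grid = grid, grid_ext = ext$grid, window = ext$window,
       extension = extension, N_ext = N_ext, N_win = N_win,
       y = y, cells = cells, n = n, A = A, pp = pp, smooth = smooth,
       idx_w = idx_w, idx_f = idx_f, idx_bm = idx_bm, idx_bp = idx_bp,
       p = p, st = st, lap_eig = lam,
       window_width = max(grid$nx, grid$ny) * grid$cell_size,
       max_dist = sqrt((grid$nx * grid$cell_size)^2 +
                         (grid$ny * grid$cell_size)^2),
       V_beta = spec$priors$fixed_variance)
}

# ---- hyperparameters -----------------------------------------------------

.theta_names <- function(spec) {
  nm <- c("theta_kappa", "theta_tau")
  if (spec$mark_family == "gamma") nm <- c(nm, "log_rho")
  if (spec$mark_family %in% c("gaussian", "lognormal"))
    nm <- c(nm, "log_prec_e")
  if (spec$preferential && spec$share_spatial) nm <- c(nm, "alpha")
  if (!is.null(spec$covariate_smooth)) nm <- c(nm, "log_rho_d")
  if (spec$preferential && spec$share_covariate) nm <- c(nm, "alpha_d")
  nm
}

# unpack the unconstrained vector (2 log kappa, log tau, ...) to natural scale
.theta_unpack <- function(par, spec) {
  nm <- .theta_names(spec)
  names(par) <- nm
  kappa <- exp(par[["theta_kappa"]] / 2)
  tau <- exp(par[["theta_tau"]])
  th <- list(kappa = kappa, tau = tau,
             range = sqrt(8) / kappa,
             sigma2 = 1 / (4 * pi * kappa^2 * tau^2),
             rho = if ("log_rho" %in% nm) exp(par[["log_rho"]]) else NULL,
             prec_e = if ("log_prec_e" %in% nm) exp(par[["log_prec_e"]])
                      else NULL,
             alpha = if ("alpha" %in% nm) par[["alpha"]]
                     else if (spec$preferential) 0 else NULL,
             rho_d = if ("log_rho_d" %in% nm) exp(par[["log_rho_d"]])
                     else NULL,
             alpha_d = if ("alpha_d" %in% nm) par[["alpha_d"]]
                       else if (spec$preferential) 0 else NULL)
  th
}

.theta_pack <- function(hyper, spec) {
  if (!is.null(hyper$range)) {
    mh <- matern_hyper(sigma2 = if (is.null(hyper$sigma2)) 1
                       else hyper$sigma2,
                       range = hyper$range)
    kappa <- mh$kappa; tau <- mh$tau
  } else {
    kappa <- hyper$kappa; tau <- hyper$tau
  }
  out <- c(theta_kappa = 2 * log(kappa), theta_tau = log(tau))
  if (spec$mark_family == "gamma")
    out <- c(out, log_rho = log(hyper$rho))
  if (spec$mark_family %in% c("gaussian", "lognormal"))
    out <- c(out, log_prec_e = log(hyper$prec_e))
  if (spec$preferential && spec$share_spatial)
    out <- c(out, alpha = hyper$alpha)
  if (!is.null(spec$covariate_smooth))
    out <- c(out, log_rho_d = log(hyper$rho_d))
  if (spec$preferential && spec$share_covariate)
    out <- c(out, alpha_d = hyper$alpha_d)
  out
}

.theta_init <- function(spec, frame) {
  y <- frame$y
  link_y <- switch(spec$mark_family,
                   gamma = log(pmax(y, 1e-8)),
                   lognormal = log(pmax(y, 1e-8)),
                   poisson = log(pmax(y, 0.5)),
                   gaussian = y)
  sig0 <- min(max(stats::sd(link_y), 0.1), 5)
  hyper <- list(range = frame$window_width / 2, sigma2 = sig0^2)
  if (spec$mark_family == "gamma") {
    r0 <- mean(y)^2 / max(stats::var(y), 1e-8)
    hyper$rho <- min(max(r0, 0.5), 50)
  }
  if (spec$mark_family %in% c("gaussian", "lognormal"))
    hyper$prec_e <- 1 / max(stats::var(link_y) / 2, 1e-4)
  if (spec$preferential && spec$share_spatial) hyper$alpha <- 1
  if (!is.null(spec$covariate_smooth)) hyper$rho_d <- 10
  if (spec$preferential && spec$share_covariate) hyper$alpha_d <- 1
  .theta_pack(hyper, spec)
}

# log prior density of the hyperparameters on the unconstrained scale
.hyper_logprior <- function(par, th, spec, frame) {
  pr <- spec$priors
  lp <- 0
  if (pr$spatial_style == "median") {
    range0 <- if (is.null(pr$range0)) frame$window_width / 2 else pr$range0
    mh0 <- matern_hyper(sigma2 = pr$sigma0^2, range = range0)
    lp <- lp + stats::dnorm(par[["theta_kappa"]], 2 * log(mh0$kappa),
                            pr$spread[1], log = TRUE) +
      stats::dnorm(par[["theta_tau"]], log(mh0$tau), pr$spread[2],
                   log = TRUE)
  } else {
    r0 <- if (is.na(pr$pc_range[1])) 0.2 * frame$max_dist else pr$pc_range[1]
    lam_r <- -log(pr$pc_range[2]) * r0
    lam_s <- -log(pr$pc_sigma[2]) / pr$pc_sigma[1]
    r <- th$range
    s <- sqrt(th$sigma2)
    # PC densities on (range, sd) plus the Jacobian |d(r,s)/d(theta)| = r*s/2
    lp <- lp + log(lam_r) - 2 * log(r) - lam_r / r +
      log(lam_s) - lam_s * s + log(r) + log(s) - log(2)
  }
  if (!is.null(th$rho))
    lp <- lp + stats::dnorm(log(th$rho), 0, 10, log = TRUE)
  if (!is.null(th$prec_e))
    lp <- lp + stats::dnorm(log(th$prec_e), 0, 10, log = TRUE)
  if (spec$preferential && spec$share_spatial)
    lp <- lp + stats::dnorm(th$alpha, 0, pr$alpha_sd, log = TRUE)
  if (spec$preferential && spec$share_covariate)
    lp <- lp + stats::dnorm(th$alpha_d, 0, pr$alpha_sd, log = TRUE)
  if (!is.null(th$rho_d)) {
    a <- pr$rho_d_prior[1]; b <- pr$rho_d_prior[2]
    ltheta <- log(th$rho_d)
    lp <- lp + a * ltheta - b * th$rho_d + a * log(b) - lgamma(a)
  }
  as.numeric(lp)
}

# ---- negative log posterior over the latent vector ----------------------

# prior precision of the full latent vector at given hyperparameters
.Q_full <- function(th, frame) {
  Qw <- .spde_Q(frame$st, th$kappa, th$tau)
  blocks <- list(Qw)
  if (!is.null(frame$smooth))
    blocks <- c(blocks, list(th$rho_d * frame$smooth$Rf +
                               frame$smooth$eps *
                                 Matrix::Diagonal(frame$smooth$m)))
  nb <- frame$p - frame$N_ext - (if (is.null(frame$smooth)) 0L
                                 else frame$smooth$m)
  blocks <- c(blocks, list(Matrix::Diagonal(nb) / frame$V_beta))
  methods::as(Matrix::forceSymmetric(Matrix::bdiag(blocks)),
              "CsparseMatrix")
}

# closed-form log-determinant of the full latent prior precision, using the
# lattice Laplacian eigenvalues (the SPDE precision is tau^2 times the
# square of kappa^2 h I + G / h)
.Q_full_logdet <- function(th, frame) {
  h <- frame$grid_ext$cell_size
  ld <- 2 * frame$N_ext * log(th$tau) +
    2 * sum(log(th$kappa^2 * h + frame$lap_eig / h))
  if (!is.null(frame$smooth))
    ld <- ld + sum(log(th$rho_d * frame$smooth$Rf_eig + frame$smooth$eps))
  nb <- frame$p - frame$N_ext - (if (is.null(frame$smooth)) 0L
                                 else frame$smooth$m)
  ld - nb * log(frame$V_beta)
}

# point-process incidence at the current sharing scales
.B_mat <- function(th, frame) {
  B <- frame$pp$B0
  if (frame$spec$share_spatial) B <- B + th$alpha * frame$pp$Bw
  if (frame$spec$share_covariate) B <- B + th$alpha_d * frame$pp$Bf
  B
}

# value / gradient / sparse Hessian of the negative log posterior of the
# latent vector at fixed hyperparameters
.nlp_eval <- function(u, th, frame, Q = NULL, B = NULL) {
  if (is.null(Q)) Q <- .Q_full(th, frame)
  fam <- .family_nll(frame$spec$mark_family, frame$y,
                     as.numeric(frame$A %*% u), th)
  Qu <- as.numeric(Q %*% u)
  value <- sum(fam$nll) + 0.5 * sum(u * Qu)
  grad <- as.numeric(Matrix::crossprod(frame$A, fam$d1)) + Qu
  H <- Q + Matrix::crossprod(frame$A, fam$d2 * frame$A)
  if (frame$spec$preferential) {
    if (is.null(B)) B <- .B_mat(th, frame)
    v <- as.numeric(B %*% u)
    Emu <- frame$pp$exposure * exp(v)
    value <- value +
      sum(Emu - frame$pp$counts * (log(frame$pp$exposure) + v) +
            lgamma(frame$pp$counts + 1))
    grad <- grad + as.numeric(Matrix::crossprod(B, Emu - frame$pp$counts))
    H <- H + Matrix::crossprod(B, Emu * B)
  }
  list(value = value, grad = grad,
       H = methods::as(Matrix::forceSymmetric(H), "CsparseMatrix"))
}

#' Joint negative log posterior of the latent vector
#'
#' Evaluates, at fixed hyperparameters, the negative unnormalised log
#' posterior of the full latent vector (extended spatial field, optional
#' RW2 smooth, intercepts): mark negative log likelihood + Poisson
#' cell-count negative log likelihood (absent for non-preferential models)
#' + the GMRF quadratic form + the Gaussian fixed-effect and smooth priors.
#' Also returns the gradient and the sparse Hessian with respect to the
#' latent vector, which are checked against finite differences in the test
#' suite.
#'
#' @param latent Numeric latent vector (length `frame dimension`; see
#'   Details of [fit_model()] for the layout).
#' @param hyper Named list of natural-scale hyperparameters: `range`,
#'   `sigma2` (or `kappa`, `tau`), plus `rho` (gamma), `prec_e`
#'   (gaussian/lognormal), `alpha`, `rho_d`, `alpha_d` as the model
#'   requires.
#' @param data A `marked_sample`.
#' @param spec A `model_spec`.
#' @param grid Grid geometry (defaults to the sample's grid).
#' @param covariate Optional covariate `latent_field` (for smooths).
#' @param extension Lattice padding in cells (defaults as in [fit_model()]).
#' @return List with `value`, `gradient`, `hessian` (sparse), and the
#'   latent dimension `p`.
#' @export
joint_neg_log_posterior <- function(latent, hyper, data, spec, grid = NULL,
                                    covariate = NULL, extension = NULL) {
  frame <- .build_frame(spec, data, grid = grid, covariate = covariate,
                        extension = extension)
  if (length(latent) != frame$p)
    stop(sprintf("latent vector has length %d, expected %d",
                 length(latent), frame$p))
  if (any(!is.finite(latent))) stop("latent vector must be finite")
  par <- .theta_pack(hyper, spec)
  th <- .theta_unpack(par, spec)
  ev <- .nlp_eval(latent, th, frame)
  list(value = ev$value, gradient = ev$grad, hessian = ev$H, p = frame$p)
}

# ---- Laplace-approximated log marginal posterior of hyperparameters ------

.theta_admissible <- function(th, frame) {
  is.finite(th$kappa) && is.finite(th$tau) &&
    th$range > 0.25 * frame$grid$cell_size &&
    th$range < 20 * frame$window_width &&
    th$sigma2 > 1e-6 && th$sigma2 < 1e6 &&
    (is.null(th$rho) || (th$rho > 1e-3 && th$rho < 1e4)) &&
    (is.null(th$prec_e) || (th$prec_e > 1e-6 && th$prec_e < 1e8)) &&
    (is.null(th$alpha) || abs(th$alpha) < 25) &&
    (is.null(th$rho_d) || (th$rho_d > 1e-8 && th$rho_d < 1e10)) &&
    (is.null(th$alpha_d) || abs(th$alpha_d) < 25)
}

# state: environment carrying the warm-start latent vector and the engine
.laplace_lp <- function(par, frame, state, tol = 1e-8, maxit = 50L) {
  th <- .theta_unpack(par, frame$spec)
  if (!.theta_admissible(th, frame)) return(-1e10)
  eng <- state$eng
  S_pp <- if (frame$spec$preferential) .S_pp(eng, th) else NULL
  nw <- tryCatch(.newton_eng(eng, state$u, th, S_pp = S_pp, tol = tol,
                             maxit = maxit),
                 error = function(e) NULL)
  if (is.null(nw) || !isTRUE(nw$converged)) return(-1e10)
  state$u <- nw$u
  logdet_H <- 2 * as.numeric(Matrix::determinant(nw$ch,
                                                 sqrt = TRUE)$modulus)
  lp <- -nw$ev$value + 0.5 * .Q_full_logdet(th, frame) - 0.5 * logdet_H +
    .hyper_logprior(par, th, frame$spec, frame)
  if (!is.finite(lp)) return(-1e10)
  state$last <- list(nw = nw, ch = nw$ch, th = th)
  lp
}

#' Fitting control parameters
#'
#' @param extension Lattice padding in cells (default: 20% of the larger
#'   grid dimension, about one default correlation range).
#' @param inner_tol Inner Newton convergence tolerance on the gradient
#'   max-norm.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param outer_maxit Maximum Nelder-Mead iterations for the hyperparameter
#'   search.
#' @param outer_reltol Relative convergence tolerance of the outer search.
#' @param hessian Compute the numeric Hessian of the hyperparameter Laplace
#'   marginal at the mode (needed for hyperparameter intervals).
#' @param integrate_hyper Average hyperparameter summaries over a coarse
#'   grid around the mode instead of reporting the mode alone.
#' @param int_k Points per hyperparameter dimension of the coarse grid
#'   (odd, default 3).
#' @param int_delta Grid step in posterior-sd units (default 1).
#' @param verbose Print progress.
#' @return A list of class `psdm_control`.
#' @export
psdm_control <- function(extension = NULL, inner_tol = 1e-8,
                         inner_maxit = 50L, outer_maxit = 400L,
                         outer_reltol = 1e-5, hessian = TRUE,
                         integrate_hyper = FALSE, int_k = 3L,
                         int_delta = 1, verbose = FALSE) {
  structure(list(extension = extension, inner_tol = inner_tol,
                 inner_maxit = as.integer(inner_maxit),
                 outer_maxit = as.integer(outer_maxit),
                 outer_reltol = outer_reltol, hessian = isTRUE(hessian),
                 integrate_hyper = isTRUE(integrate_hyper),
                 int_k = as.integer(int_k), int_delta = int_delta,
                 verbose = isTRUE(verbose)),
            class = "psdm_control")
}

#' Fit a preferential or non-preferential spatial abundance model
#'
#' Empirical-Bayes Laplace inference for the latent Gaussian model declared
#' by `spec`. The inner loop maximises the joint posterior of the latent
#' vector (extended SPDE field, optional RW2 smooth, intercepts) by Newton
#' iterations with sparse Cholesky solves and step halving; the outer loop
#' maximises the Laplace-approximated log marginal posterior of the
#' hyperparameters by Nelder-Mead from deterministic initial values (field
#' range at half the window; intercepts at link transforms of the mark
#' mean; sharing scale at 1). Latent marginal standard deviations come from
#' the Gaussian approximation at the hyperparameter mode; optionally a
#' coarse hyperparameter grid around the mode yields weighted posterior
#' means and sds of the hyperparameters.
#'
#' @param spec A [model_spec()].
#' @param data A `marked_sample`.
#' @param grid A `grid_geometry` (defaults to the sample's grid).
#' @param covariate Optional covariate surface (`latent_field`) when the
#'   spec has a covariate smooth.
#' @param control A [psdm_control()].
#' @return An object of class `psdm_fit`; see [predict_surface()],
#'   [compute_dic()], [compute_lcpo()].
#' @export
fit_model <- function(spec, data, grid = NULL, covariate = NULL,
                      control = psdm_control()) {
  stopifnot(inherits(control, "psdm_control"))
  frame <- .build_frame(spec, data, grid = grid, covariate = covariate,
                        extension = control$extension)
  fit <- .fit_frame(frame, control)
  fit$data <- data
  fit$covariate <- covariate
  fit
}

# core fitter over a prebuilt frame (also used by exact leave-one-out,
# which perturbs the mark rows of a frame while keeping the point pattern)
.fit_frame <- function(frame, control, par0 = NULL) {
  spec <- frame$spec
  # deterministic initial latent vector: zero field, link-scale intercepts
  u0 <- numeric(frame$p)
  link_mean <- switch(spec$mark_family,
                      gamma = log(mean(frame$y)),
                      lognormal = mean(log(frame$y)),
                      poisson = log(mean(frame$y) + 0.5),
                      gaussian = mean(frame$y))
  u0[frame$idx_bm] <- link_mean
  if (spec$preferential)
    u0[frame$idx_bp] <- log(frame$n /
                              (frame$N_win * frame$grid$cell_size^2))

  state <- new.env(parent = emptyenv())
  state$u <- u0
  state$eng <- .make_engine(frame)
  if (is.null(par0)) par0 <- .theta_init(spec, frame)
  fn <- function(p) -.laplace_lp(p, frame, state, tol = control$inner_tol,
                                 maxit = control$inner_maxit)
  v0 <- fn(par0)
  if (v0 >= 1e10)
    stop("model fit failed at the initial hyperparameters (inner Newton ",
         "did not converge); check marks and model specification")
  opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                      control = list(maxit = control$outer_maxit,
                                     reltol = control$outer_reltol))
  par_hat <- opt$par
  lp_hat <- -opt$value
  # final evaluation at the mode to refresh the cached Newton state
  lp_final <- .laplace_lp(par_hat, frame, state, tol = control$inner_tol,
                          maxit = control$inner_maxit)
  if (lp_final <= -1e10)
    stop("inner Newton failed to converge at the hyperparameter mode")
  fin <- state$last
  th <- fin$th

  theta_vcov <- NULL
  if (control$hessian) {
    Hh <- tryCatch(stats::optimHess(par_hat, fn), error = function(e) NULL)
    if (!is.null(Hh)) {
      theta_vcov <- tryCatch(solve(Hh), error = function(e) NULL)
      if (!is.null(theta_vcov) && any(diag(theta_vcov) <= 0))
        theta_vcov <- NULL
      if (!is.null(theta_vcov))
        dimnames(theta_vcov) <- list(.theta_names(spec),
                                     .theta_names(spec))
    }
  }

  hyper_grid <- NULL
  if (control$integrate_hyper && !is.null(theta_vcov)) {
    sds <- sqrt(diag(theta_vcov))
    offs <- control$int_delta * seq(-(control$int_k %/% 2),
                                    control$int_k %/% 2)
    pts <- as.matrix(expand.grid(rep(list(offs), length(par_hat))))
    lps <- apply(pts, 1, function(o) {
      .laplace_lp(par_hat + o * sds, frame, state,
                  tol = control$inner_tol, maxit = control$inner_maxit)
    })
    keep <- lps > -1e9
    wts <- exp(lps[keep] - max(lps[keep]))
    wts <- wts / sum(wts)
    theta_pts <- sweep(pts[keep, , drop = FALSE], 2, sds, "*") +
      matrix(par_hat, nrow = sum(keep), ncol = length(par_hat),
             byrow = TRUE)
    nat <- t(apply(theta_pts, 1, function(pp) {
      tt <- .theta_unpack(pp, spec)
      c(range = tt$range, sigma2 = tt$sigma2,
        alpha = if (is.null(tt$alpha)) NA_real_ else tt$alpha,
        rho = if (is.null(tt$rho)) NA_real_ else tt$rho)
    }))
    post_mean <- colSums(nat * wts)
    post_sd <- sqrt(pmax(colSums(nat^2 * wts) - post_mean^2, 0))
    hyper_grid <- list(points = theta_pts, weights = wts,
                       mean = post_mean, sd = post_sd)
    # refresh cached state at the mode
    .laplace_lp(par_hat, frame, state, tol = control$inner_tol,
                maxit = control$inner_maxit)
    fin <- state$last
  }

  # latent marginal sds (window field cells, smooth, intercepts) from the
  # Gaussian approximation at the mode: diag of H^-1 by sparse triangular
  # solves
  sel <- c(frame$window, frame$idx_f, frame$idx_bm, frame$idx_bp)
  S <- Matrix::sparseMatrix(i = sel, j = seq_along(sel), x = 1,
                            dims = c(frame$p, length(sel)))
  y1 <- Matrix::solve(fin$ch, S, system = "P")
  y2 <- Matrix::solve(fin$ch, y1, system = "L")
  marg_var <- Matrix::colSums(y2^2)
  latent_sd <- sqrt(as.numeric(marg_var))
  names(latent_sd) <- c(paste0("w", seq_len(frame$N_win)),
                        if (length(frame$idx_f))
                          paste0("f", seq_along(frame$idx_f)),
                        "beta_mark",
                        if (length(frame$idx_bp)) "beta_pp")

  # confounding check for the experimental fully shared model
  confounding <- FALSE
  if (spec$preferential && spec$share_covariate && spec$share_spatial) {
    sf <- fin$nw$u[frame$idx_f][frame$smooth$bin_cell]
    sw <- fin$nw$u[frame$window]
    cc <- suppressWarnings(stats::cor(sf, sw))
    # two confounding symptoms: the shared components are collinear, or
    # the smooth has absorbed the spatial field entirely (degenerate w)
    collinear <- is.finite(cc) && abs(cc) > 0.9
    absorbed <- stats::sd(sw) < 0.05 * stats::sd(sf)
    if (collinear || absorbed) {
      confounding <- TRUE
      warning("the shared covariate smooth and the shared spatial field ",
              "carry the same information (",
              if (collinear) sprintf("component correlation %.2f", cc)
              else "the smooth has absorbed the field",
              "); the fully shared model is likely unidentifiable")
    }
  }

  fam_par <- list(rho = th$rho, prec_e = th$prec_e)
  eta_hat <- as.numeric(frame$A %*% fin$nw$u)
  dev_i <- 2 * .family_nll(spec$mark_family, frame$y, eta_hat,
                           fam_par)$nll

  structure(list(
    spec = spec, frame = frame, control = control,
    theta = par_hat, theta_list = th, theta_vcov = theta_vcov,
    hyper_grid = hyper_grid,
    hyper_summary = data.frame(
      parameter = c("range", "sigma2",
                    if (!is.null(th$rho)) "rho",
                    if (!is.null(th$prec_e)) "prec_e",
                    if (spec$preferential && spec$share_spatial) "alpha",
                    if (!is.null(th$rho_d)) "rho_d",
                    if (spec$preferential && spec$share_covariate)
                      "alpha_d"),
      mode = c(th$range, th$sigma2, th$rho, th$prec_e,
               if (spec$preferential && spec$share_spatial) th$alpha,
               th$rho_d,
               if (spec$preferential && spec$share_covariate) th$alpha_d)),
    latent_mode = fin$nw$u, latent_sd = latent_sd,
    chol = fin$ch, log_marg_lik = lp_hat,
    deviance_i = dev_i, eta_hat = eta_hat,
    converged = TRUE, confounding = confounding,
    convergence = list(outer_value = lp_hat,
                       outer_counts = opt$counts,
                       outer_convergence = opt$convergence,
                       inner_iters = fin$nw$iters,
                       inner_grad_norm = fin$nw$grad_norm)),
    class = "psdm_fit")
}

#' @export
print.psdm_fit <- function(x, ...) {
  cat(sprintf("<psdm_fit> %s model, %s marks, n = %d\n",
              if (x$spec$preferential) "preferential" else
                "non-preferential",
              x$spec$mark_family, x$frame$n))
  print(x$hyper_summary, row.names = FALSE)
  invisible(x)
}
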