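# Fast evaluation engine for the latent-vector negative log posterior.
#
# All sparsity patterns in the problem are fixed across hyperparameter and
# Newton iterations: the SPDE precision lives on the 13-point lattice
# stencil, the likelihood Hessian contributions touch at most 3 latent
# coordinates per observation/cell, and their union gives one symmetric
# template pattern T. The engine precomputes, once per model frame,
# (a) the positions of every component's nonzeros inside T@x, and
# (b) aggregation matrices mapping per-observation / per-cell second
# derivatives onto T@x, so that each Hessian assembly is pure numeric
# vector arithmetic followed by a CHOLMOD numeric refactorisation with a
# cached symbolic analysis.

# upper-triangle (i, j, x) of a symmetric sparse matrix, 0-based, with keys
.upper_ijx <- function(M, dim_key) {
  M <- methods::as(Matrix::forceSymmetric(methods::as(M, "CsparseMatrix")),
                   "symmetricMatrix")
  M <- methods::as(M, "CsparseMatrix")   # dsCMatrix, uplo "U"
  j <- rep.int(seq_len(ncol(M)), diff(M@p)) - 1L
  list(i = M@i, j = j, x = M@x,
       key = as.numeric(M@i) + as.numeric(j) * dim_key)
}

# position in the template of upper-triangle pairs (a, b) with a <= b,
# given 1-based coordinates
.tpos <- function(a, b, tkey, dim_key) {
  lo <- pmin(a, b) - 1
  hi <- pmax(a, b) - 1
  pos <- match(lo + hi * dim_key, tkey)
  if (any(is.na(pos)))
    stop("internal error: entry missing from the Hessian template")
  pos
}

.make_engine <- function(frame) {
  spec <- frame$spec
  p <- frame$p
  N_ext <- frame$N_ext
  G <- frame$st$G
  G2 <- frame$st$G2
  h <- frame$grid_ext$cell_size
  has_f <- !is.null(frame$smooth)
  m_f <- if (has_f) frame$smooth$m else 0L

  obs_w <- frame$window[frame$cells]
  obs_f <- if (has_f) frame$idx_f[frame$smooth$bin_obs] else NULL
  cell_f <- if (has_f) frame$idx_f[frame$smooth$bin_cell] else NULL

  # ---- template pattern: positive-valued stand-ins of every component ----
  absG <- abs(G)
  Qpat <- Matrix::Diagonal(N_ext) + 2 * absG + abs(G2)
  blocks <- list(Qpat)
  if (has_f)
    blocks <- c(blocks, list(abs(frame$smooth$Rf) +
                               Matrix::Diagonal(m_f)))
  nb <- p - N_ext - m_f
  blocks <- c(blocks, list(Matrix::Diagonal(nb)))
  Tpat <- Matrix::bdiag(blocks)
  Apat <- Matrix::crossprod(frame$A)
  Tpat <- Tpat + Apat
  if (spec$preferential) {
    Ball <- frame$pp$B0
    if (spec$share_spatial) Ball <- Ball + frame$pp$Bw
    if (spec$share_covariate) Ball <- Ball + frame$pp$Bf
    Tpat <- Tpat + Matrix::crossprod(Ball)
  }
  T0 <- methods::as(Matrix::forceSymmetric(Tpat), "CsparseMatrix")
  T0@x[] <- 0
  T0@factors <- list()
  tk <- .upper_ijx(T0, p)
  tkey <- tk$key
  nnzT <- length(tkey)

  # ---- SPDE block maps: identity / G / G^2 aligned to the G^2 pattern ----
  g2u <- .upper_ijx(G2, p)            # block occupies coords 1..N_ext
  posQ <- match(g2u$key, tkey)
  vI <- as.numeric(g2u$i == g2u$j)
  gu <- .upper_ijx(G, p)
  vG <- numeric(length(posQ))
  vG[match(gu$key, g2u$key)] <- gu$x
  vG2 <- g2u$x

  # ---- smooth and intercept blocks ----
  pos_Rf <- NULL; val_Rf <- NULL; pos_fdiag <- NULL
  if (has_f) {
    fu <- .upper_ijx(frame$smooth$Rf, p)
    off <- N_ext
    pos_Rf <- .tpos(fu$i + 1L + off, fu$j + 1L + off, tkey, p)
    val_Rf <- fu$x
    pos_fdiag <- .tpos(off + seq_len(m_f), off + seq_len(m_f), tkey, p)
  }
  idx_b <- c(frame$idx_bm, frame$idx_bp)
  pos_bdiag <- .tpos(idx_b, idx_b, tkey, p)
  pos_alldiag <- .tpos(seq_len(p), seq_len(p), tkey, p)

  # ---- mark-likelihood aggregation: T@x += S_A %*% d2_mark ----
  lik_pairs <- function(cols_list) {
    ii <- integer(0); jj <- integer(0)
    for (k in seq_along(cols_list)) {
      cols <- cols_list[[k]]
      pr <- which(upper.tri(diag(length(cols)), diag = TRUE),
                  arr.ind = TRUE)
      ii <- c(ii, .tpos(cols[pr[, 1]], cols[pr[, 2]], tkey, p))
      jj <- c(jj, rep.int(k, nrow(pr)))
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                         dims = c(nnzT, length(cols_list)))
  }
  cols_obs <- lapply(seq_len(frame$n), function(i)
    c(obs_w[i], if (has_f) obs_f[i], frame$idx_bm))
  S_A <- lik_pairs(cols_obs)

  # ---- point-process aggregation, split by sharing-scale product ----
  S_pp_parts <- NULL
  if (spec$preferential) {
    N_win <- frame$N_win
    mk <- function(a, b) {
      pos <- .tpos(a, b, tkey, p)
      Matrix::sparseMatrix(i = pos, j = seq_len(N_win), x = 1,
                           dims = c(nnzT, N_win))
    }
    w_ <- frame$window
    b_ <- rep(frame$idx_bp, N_win)
    S_pp_parts <- list(bb = mk(b_, b_))
    if (spec$share_spatial) {
      S_pp_parts$ww <- mk(w_, w_)
      S_pp_parts$wb <- mk(w_, b_)
    }
    if (spec$share_covariate) {
      S_pp_parts$ff <- mk(cell_f, cell_f)
      S_pp_parts$fb <- mk(cell_f, b_)
      if (spec$share_spatial) S_pp_parts$wf <- mk(w_, cell_f)
    }
  }

  list2env(
    list(frame = frame, p = p, N_ext = N_ext, h = h,
         has_f = has_f, m_f = m_f, nb = nb,
         obs_w = obs_w, obs_f = obs_f, cell_f = cell_f,
         G = G, G2 = G2, Rf = if (has_f) frame$smooth$Rf else NULL,
         T0 = T0, nnzT = nnzT,
         posQ = posQ, vI = vI, vG = vG, vG2 = vG2,
         pos_Rf = pos_Rf, val_Rf = val_Rf, pos_fdiag = pos_fdiag,
         pos_bdiag = pos_bdiag, pos_alldiag = pos_alldiag,
         S_A = S_A, S_pp_parts = S_pp_parts,
         symb = NULL),
    parent = emptyenv())
}

# Newton maximisation of the latent posterior through the engine
.newton_eng <- function(eng, u0, th, S_pp = NULL, tol = 1e-8,
                        maxit = 50L) {
  u <- u0
  ev <- .eng_value_grad(eng, u, th)
  iters <- 0L
  for (it in seq_len(maxit)) {
    if (max(abs(ev$grad)) < tol) break
    H <- .eng_hess(eng, th, ev$d2m, ev$dp, S_pp)
    ch <- .eng_chol(eng, H)
    ridge <- 0
    while (is.null(ch) && ridge < 1e6) {
      ridge <- if (ridge == 0) 1e-6 else ridge * 100
      ch <- .eng_chol(eng, .eng_hess(eng, th, ev$d2m, ev$dp, S_pp,
                                     ridge = ridge))
    }
    if (is.null(ch))
      return(list(converged = FALSE, u = u, reason = "hessian not pd"))
    delta <- -as.numeric(Matrix::solve(ch, ev$grad, system = "A"))
    step <- 1
    repeat {
      u_new <- u + step * delta
      ev_new <- .eng_value_grad(eng, u_new, th)
      if (is.finite(ev_new$value) && ev_new$value <= ev$value + 1e-10)
        break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12)
      return(list(converged = max(abs(ev$grad)) < tol * 100, u = u,
                  ev = ev, iters = it, grad_norm = max(abs(ev$grad)),
                  reason = "line search stalled"))
    u <- u_new
    ev <- ev_new
    iters <- it
  }
  converged <- max(abs(ev$grad)) < tol
  if (!converged)
    return(list(converged = FALSE, u = u, ev = ev, iters = iters,
                grad_norm = max(abs(ev$grad)),
                reason = "max iterations reached"))
  H <- .eng_hess(eng, th, ev$d2m, ev$dp, S_pp)
  ch <- .eng_chol(eng, H)
  if (is.null(ch))
    return(list(converged = FALSE, u = u, ev = ev, iters = iters,
                reason = "hessian not pd at mode"))
  list(converged = TRUE, u = u, ev = ev, H = H, ch = ch, iters = iters,
       grad_norm = max(abs(ev$grad)))
}

# point-process aggregation matrix at the current sharing scales
.S_pp <- function(eng, th) {
  parts <- eng$S_pp_parts
  S <- parts$bb
  if (!is.null(parts$ww))
    S <- S + th$alpha^2 * parts$ww + th$alpha * parts$wb
  if (!is.null(parts$ff)) {
    S <- S + th$alpha_d^2 * parts$ff + th$alpha_d * parts$fb
    if (!is.null(parts$wf)) S <- S + th$alpha * th$alpha_d * parts$wf
  }
  S
}

# value + gradient (+ family derivative vectors) at u; no Hessian
.eng_value_grad <- function(eng, u, th) {
  frame <- eng$frame
  spec <- frame$spec
  w <- u[seq_len(eng$N_ext)]
  f <- if (eng$has_f) u[frame$idx_f] else NULL
  fam_par <- list(rho = th$rho, prec_e = th$prec_e)

  eta <- u[eng$obs_w] + u[frame$idx_bm]
  if (eng$has_f) eta <- eta + u[eng$obs_f]
  fam <- .family_nll(spec$mark_family, frame$y, eta, fam_par)

  # prior quadratic form and its gradient
  qw <- th$tau^2 * (th$kappa^4 * eng$h^2 * w +
                      2 * th$kappa^2 * as.numeric(eng$G %*% w) +
                      as.numeric(eng$G2 %*% w) / eng$h^2)
  grad <- numeric(eng$p)
  grad[seq_len(eng$N_ext)] <- qw
  quad <- sum(w * qw)
  if (eng$has_f) {
    qf <- th$rho_d * as.numeric(eng$Rf %*% f) + frame$smooth$eps * f
    grad[frame$idx_f] <- qf
    quad <- quad + sum(f * qf)
  }
  idx_b <- c(frame$idx_bm, frame$idx_bp)
  qb <- u[idx_b] / frame$V_beta
  grad[idx_b] <- grad[idx_b] + qb
  quad <- quad + sum(u[idx_b] * qb)

  value <- sum(fam$nll) + 0.5 * quad
  # mark likelihood gradient (scatter-add; observations may share cells)
  agg <- rowsum(fam$d1, eng$obs_w)
  grad[as.integer(rownames(agg))] <-
    grad[as.integer(rownames(agg))] + agg[, 1]
  grad[frame$idx_bm] <- grad[frame$idx_bm] + sum(fam$d1)
  if (eng$has_f) {
    aggf <- rowsum(fam$d1, eng$obs_f)
    grad[as.integer(rownames(aggf))] <-
      grad[as.integer(rownames(aggf))] + aggf[, 1]
  }

  dp <- NULL
  if (spec$preferential) {
    v <- u[frame$idx_bp] +
      (if (spec$share_spatial) th$alpha * u[frame$window] else 0) +
      (if (spec$share_covariate) th$alpha_d * u[eng$cell_f] else 0)
    Emu <- frame$pp$exposure * exp(v)
    value <- value +
      sum(Emu - frame$pp$counts * (log(frame$pp$exposure) + v) +
            lgamma(frame$pp$counts + 1))
    d1p <- Emu - frame$pp$counts
    grad[frame$idx_bp] <- grad[frame$idx_bp] + sum(d1p)
    if (spec$share_spatial)
      grad[frame$window] <- grad[frame$window] + th$alpha * d1p
    if (spec$share_covariate) {
      aggp <- rowsum(d1p, eng$cell_f)
      grad[as.integer(rownames(aggp))] <-
        grad[as.integer(rownames(aggp))] + th$alpha_d * aggp[, 1]
    }
    dp <- Emu
  }
  list(value = value, grad = grad, d2m = fam$d2, dp = dp)
}

# assemble the sparse Hessian template values
.eng_hess <- function(eng, th, d2m, dp, S_pp = NULL, ridge = 0) {
  x <- numeric(eng$nnzT)
  x[eng$posQ] <- th$tau^2 * (th$kappa^4 * eng$h^2 * eng$vI +
                               2 * th$kappa^2 * eng$vG +
                               eng$vG2 / eng$h^2)
  if (eng$has_f) {
    x[eng$pos_Rf] <- x[eng$pos_Rf] + th$rho_d * eng$val_Rf
    x[eng$pos_fdiag] <- x[eng$pos_fdiag] + eng$frame$smooth$eps
  }
  x[eng$pos_bdiag] <- x[eng$pos_bdiag] + 1 / eng$frame$V_beta
  x <- x + as.numeric(eng$S_A %*% d2m)
  if (!is.null(dp)) {
    if (is.null(S_pp)) S_pp <- .S_pp(eng, th)
    x <- x + as.numeric(S_pp %*% dp)
  }
  if (ridge > 0) x[eng$pos_alldiag] <- x[eng$pos_alldiag] + ridge
  H <- eng$T0
  H@x <- x
  H
}

# numeric Cholesky with cached symbolic analysis; NULL on failure
.eng_chol <- function(eng_env, H) {
  ok <- TRUE
  ch <- tryCatch(
    withCallingHandlers({
      if (is.null(eng_env$symb))
        Matrix::Cholesky(H, LDL = FALSE, perm = TRUE, super = TRUE)
      else Matrix::update(eng_env$symb, H)
    }, warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    }),
    error = function(e) NULL)
  if (is.null(ch) || !ok) return(NULL)
  if (is.null(eng_env$symb)) eng_env$symb <- ch
  ch
}
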