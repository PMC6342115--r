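# Joint model: point-pattern binning, negative log posterior, RW2, fitting.

test_that("point patterns bin onto the lattice with conserved counts", {
  g <- grid_geometry(8, 8)
  loc <- data.frame(cell = c(3L, 3L, 10L, 64L))
  bp <- bin_point_pattern(loc, g)
  expect_identical(sum(bp$counts), 4L)
  expect_identical(bp$counts[3], 2L)
  expect_identical(bp$exposure, rep(1, 64))
  expect_identical(bin_point_pattern(data.frame(cell = integer(0)),
                                     g)$counts, integer(64))
  single <- bin_point_pattern(data.frame(cell = 17L), g)$counts
  expect_identical(which(single > 0), 17L)
  expect_identical(single[17], 1L)
  expect_error(bin_point_pattern(data.frame(cell = 65L), g), "outside")
})

test_that("the joint negative log posterior decomposes into its terms", {
  s <- tiny_scenario(seed = 31, nx = 6, range = 2, n = 15)
  spec <- model_spec("gamma", preferential = TRUE)
  hyper <- list(range = 2.5, sigma2 = 0.8, rho = 7, alpha = 0.9)
  ext <- extend_grid(s$grid, 1L)
  N <- n_cells(ext$grid)
  set.seed(40)
  u <- c(rnorm(N, sd = 0.3), 0.4, -2.1)   # field, mark and pp intercepts
  res <- joint_neg_log_posterior(u, hyper, s$preferential, spec,
                                 extension = 1)
  # hand-computed components
  w <- u[1:N]
  cells <- s$preferential$data$cell
  y <- s$preferential$data$mark
  eta <- u[N + 1] + w[ext$window[cells]]
  mark_nll <- -sum(dgamma(y, shape = 7, rate = 7 / exp(eta), log = TRUE))
  counts <- tabulate(cells, 36)
  v <- u[N + 2] + 0.9 * w[ext$window]
  pp_nll <- -sum(dpois(counts, exp(v), log = TRUE))
  Q <- spde_precision(s$grid, matern_hyper(0.8, 2.5), extension = 1)$Q
  quad <- 0.5 * as.numeric(t(w) %*% Q %*% w)
  betas <- 0.5 * (u[N + 1]^2 + u[N + 2]^2) / 100
  expect_equal(res$value, mark_nll + pp_nll + quad + betas,
               tolerance = 1e-10)
  # the non-preferential posterior drops exactly the point-process term
  spec0 <- model_spec("gamma", preferential = FALSE)
  res0 <- joint_neg_log_posterior(u[1:(N + 1)], hyper, s$preferential,
                                  spec0, extension = 1)
  expect_equal(res0$value, mark_nll + quad + 0.5 * u[N + 1]^2 / 100,
               tolerance = 1e-10)
  expect_error(joint_neg_log_posterior(u[-1], hyper, s$preferential, spec,
                                       extension = 1), "length")
  expect_error(joint_neg_log_posterior(replace(u, 1, NA), hyper,
                                       s$preferential, spec,
                                       extension = 1), "finite")
})

test_that("doubling exposure while halving intensity leaves the Poisson
           term invariant", {
  s <- tiny_scenario(seed = 31, nx = 6, range = 2, n = 15)
  spec <- model_spec("gamma", preferential = TRUE)
  hyper <- list(range = 2.5, sigma2 = 0.8, rho = 7, alpha = 0.9)
  frame <- prefsdm:::.build_frame(spec, s$preferential, extension = 1)
  th <- prefsdm:::.theta_unpack(prefsdm:::.theta_pack(hyper, spec), spec)
  set.seed(41)
  u <- c(rnorm(frame$N_ext, sd = 0.3), 0.2, -1.5)
  v1 <- prefsdm:::.nlp_eval(u, th, frame)$value
  frame2 <- frame
  frame2$pp$exposure <- 2 * frame$pp$exposure
  u2 <- u
  u2[frame$idx_bp] <- u[frame$idx_bp] - log(2)   # halve the intensity
  v2 <- prefsdm:::.nlp_eval(u2, th, frame2)$value
  # identical Poisson terms; only the intercept prior shifts
  prior_shift <- 0.5 * (u2[frame$idx_bp]^2 - u[frame$idx_bp]^2) / 100
  expect_equal(v2 - v1, prior_shift, tolerance = 1e-10)
})

test_that("gradient and Hessian pass finite-difference checks", {
  for (seed in c(31, 32)) {
    s <- tiny_scenario(seed = seed, nx = 6, range = 2, n = 15)
    spec <- model_spec("gamma", preferential = TRUE)
    hyper <- list(range = 2.5, sigma2 = 0.8, rho = 7, alpha = 0.9)
    ext <- extend_grid(s$grid, 1L)
    N <- n_cells(ext$grid)
    set.seed(seed)
    u <- c(rnorm(N, sd = 0.3), 0.4, -2.1)
    res <- joint_neg_log_posterior(u, hyper, s$preferential, spec,
                                   extension = 1)
    f <- function(uu) joint_neg_log_posterior(uu, hyper, s$preferential,
                                              spec, extension = 1)$value
    fd <- fd_gradient(f, u)
    expect_lt(max(abs(fd - res$gradient)) / max(abs(res$gradient)), 1e-4)
    # Hessian columns vs finite differences of the gradient
    gfun <- function(uu) joint_neg_log_posterior(uu, hyper,
                                                 s$preferential, spec,
                                                 extension = 1)$gradient
    for (j in c(1L, N %/% 2L, N + 1L, N + 2L)) {
      h <- 1e-5
      up <- u; up[j] <- up[j] + h
      um <- u; um[j] <- um[j] - h
      fd_col <- (gfun(up) - gfun(um)) / (2 * h)
      expect_lt(max(abs(fd_col - res$hessian[, j])),
                1e-4 * max(1, max(abs(fd_col))))
    }
  }
})

test_that("the fast engine reproduces the reference posterior exactly", {
  s <- tiny_scenario(seed = 33, nx = 8, range = 3, n = 25)
  spec <- model_spec("gamma", preferential = TRUE)
  hyper <- list(range = 3, sigma2 = 1, rho = 9, alpha = 1.1)
  frame <- prefsdm:::.build_frame(spec, s$preferential, extension = 2)
  eng <- prefsdm:::.make_engine(frame)
  th <- prefsdm:::.theta_unpack(prefsdm:::.theta_pack(hyper, spec), spec)
  set.seed(50)
  u <- rnorm(frame$p, sd = 0.4)
  ref <- prefsdm:::.nlp_eval(u, th, frame)
  ev <- prefsdm:::.eng_value_grad(eng, u, th)
  H <- prefsdm:::.eng_hess(eng, th, ev$d2m, ev$dp)
  expect_equal(ev$value, ref$value, tolerance = 1e-12)
  expect_equal(ev$grad, ref$grad, tolerance = 1e-10)
  expect_lt(max(abs(H - ref$H)), 1e-10)
})

test_that("RW2 precision penalises curvature only and is scaled", {
  Q <- build_rw2_precision(12)
  m <- 12L
  expect_lt(max(abs(Q %*% rep(1, m))), 1e-10)
  expect_lt(max(abs(Q %*% seq_len(m))), 1e-9)
  expect_gt(max(abs(Q %*% (seq_len(m)^2))), 1e-6)
  expect_identical(as.integer(Matrix::rankMatrix(as.matrix(Q))), m - 2L)
  # generalized variance 1: geometric mean of proper-part marginal variances
  e <- eigen(as.matrix(Q), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  V <- e$vectors[, pos, drop = FALSE]
  Sig <- V %*% (t(V) / e$values[pos])
  expect_equal(exp(mean(log(diag(Sig)))), 1, tolerance = 1e-10)
  expect_error(build_rw2_precision(2))
})

test_that("model specifications enforce their invariants", {
  expect_error(model_spec("gamma", preferential = TRUE,
                          share_spatial = FALSE),
               "share at least one component")
  expect_error(model_spec("gamma", share_covariate = TRUE),
               "covariate_smooth")
  sp <- model_spec("gamma", preferential = FALSE)
  expect_false(sp$share_spatial)
  expect_error(model_spec("weibull"))
})

test_that("fitting recovers a sensible preferential model on simulated
           data", {
  s <- tiny_scenario(seed = 42, nx = 16, range = 4, n = 60)
  fit <- fit_model(model_spec("gamma"), s$preferential,
                   control = fast_control())
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$hyper_summary$mode)))
  expect_gt(fit$theta_list$alpha, 0)      # positive sharing, as generated
  expect_true(all(fit$latent_sd > 0))
  pred <- predict_surface(fit)
  expect_true(all(pred$mean$values > 0))  # log link positivity
  sc <- cor(pred$mean$values[s$preferential$data$cell],
            s$preferential$data$mark, method = "spearman")
  expect_gt(sc, 0)
  # empty data and non-positive gamma marks are rejected
  bad <- s$preferential
  bad$data <- bad$data[0, ]
  expect_error(fit_model(model_spec("gamma"), bad), "empty")
  bad2 <- s$preferential
  bad2$data$mark[1] <- -1
  expect_error(fit_model(model_spec("gamma"), bad2), "positive")
})

test_that("the non-preferential fit ignores the sampling design", {
  s <- tiny_scenario(seed = 43, nx = 12, range = 3, n = 40)
  spec <- model_spec("gamma", preferential = FALSE)
  f1 <- fit_model(spec, s$preferential, control = fast_control())
  # same marks at the same cells presented as a different design
  relabeled <- s$preferential
  relabeled$design <- sample_design("uniform", n = 40)
  f2 <- fit_model(spec, relabeled, control = fast_control())
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$latent_mode, f2$latent_mode)
  expect_identical(predict_surface(f1)$mean$values,
                   predict_surface(f2)$mean$values)
})

test_that("the lognormal mean correction is used for prediction", {
  pm <- predictive_mean(m = c(0, 1), v = c(0, 0), family = "gamma")
  expect_identical(pm$mean, exp(c(0, 1)))   # v = 0 limit: exp(mode) exactly
  expect_identical(pm$sd, c(0, 0))
  pm2 <- predictive_mean(1, 0.5, family = "gamma")
  expect_equal(pm2$mean, exp(1.25))
  pg <- predictive_mean(1.5, 0.4, family = "gaussian")
  expect_identical(pg$mean, 1.5)
  expect_error(predictive_mean(0, -1, "gamma"))
})

test_that("all mark families fit and predict on their own scale", {
  g <- small_grid(12)
  field <- simulate_grf(g, matern_hyper(0.5, 4), seed = 200)
  loc <- uniform_sample(g, 70, seed = 201)
  eta <- 0.8 + field$values[loc$cell]
  set.seed(202)
  obs <- list(
    gaussian = eta + rnorm(70, sd = 0.3),
    lognormal = exp(eta + rnorm(70, sd = 0.3)),
    poisson = rpois(70, exp(eta))
  )
  for (fam in names(obs)) {
    dat <- prefsdm:::new_marked_sample(
      data.frame(x = loc$x, y = loc$y, cell = loc$cell, mark = obs[[fam]]),
      design = attr(loc, "design"), family = fam, grid = g)
    fit <- fit_model(model_spec(fam, preferential = FALSE), dat,
                     control = fast_control())
    expect_true(fit$converged)
    pred <- predict_surface(fit)
    if (fam == "gaussian") {
      expect_gt(cor(pred$mean$values, 0.8 + field$values), 0.5)
    } else {
      expect_true(all(pred$mean$values > 0))
      expect_gt(cor(log(pred$mean$values), 0.8 + field$values), 0.5)
    }
    d <- compute_dic(fit, S = 200, seed = 3)
    expect_identical(d$dic, d$dbar + d$pd)
  }
})

test_that("coarse-grid hyperparameter integration yields weighted
           posterior summaries", {
  s <- tiny_scenario(seed = 210, nx = 10, range = 3, n = 30)
  fit <- fit_model(model_spec("gamma", preferential = FALSE),
                   s$preferential,
                   control = psdm_control(hessian = TRUE,
                                          integrate_hyper = TRUE))
  hg <- fit$hyper_grid
  expect_false(is.null(hg))
  expect_equal(sum(hg$weights), 1, tolerance = 1e-12)
  expect_true(all(is.finite(hg$mean[c("range", "sigma2")])))
  expect_true(all(hg$sd[c("range", "sigma2")] > 0))
  # the weighted posterior mean stays in the vicinity of the mode
  expect_lt(abs(hg$mean[["range"]] - fit$theta_list$range),
            3 * hg$sd[["range"]] + 1e-8)
})
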