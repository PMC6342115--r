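# Scoring: DIC, LCPO, MAE.

test_that("DIC identities hold by construction", {
  s <- tiny_scenario(seed = 61, nx = 10, range = 3, n = 30)
  fit <- fit_model(model_spec("gamma"), s$preferential,
                   control = fast_control())
  d <- compute_dic(fit, S = 400, seed = 8)
  expect_identical(d$dic, d$dbar + d$pd)
  expect_gt(d$pd, 0)
  # a point-mass (zero-variance) posterior has no effective parameters
  y <- s$preferential$data$mark
  eta_hat <- log(pmax(y, 0.5))
  draws <- matrix(eta_hat, length(y), 50)
  d0 <- dic_from_draws(y, draws, eta_hat, "gamma", list(rho = 5))
  expect_identical(d0$pd, 0)
  expect_identical(d0$dic, d0$dbar)
})

test_that("DIC matches the closed form of a conjugate normal model", {
  # y_i ~ N(mu, s2) with known s2, mu ~ N(0, v0): everything is closed form
  set.seed(71)
  n <- 40; s2 <- 2; v0 <- 10
  y <- rnorm(n, 1.3, sqrt(s2))
  v_post <- 1 / (n / s2 + 1 / v0)
  m_post <- v_post * sum(y) / s2
  dhat <- n * log(2 * pi * s2) + sum((y - m_post)^2) / s2
  pd_true <- n * v_post / s2
  dic_true <- dhat + 2 * pd_true
  S <- 200000
  mu_s <- rnorm(S, m_post, sqrt(v_post))
  d <- dic_from_draws(y, matrix(mu_s, n, S, byrow = TRUE),
                      rep(m_post, n), "gaussian", list(prec_e = 1 / s2))
  # Monte Carlo tolerance from the per-draw deviances themselves
  dev_sub <- n * log(2 * pi * s2) +
    vapply(mu_s[1:5000], function(m) sum((y - m)^2), numeric(1)) / s2
  se <- sd(dev_sub) / sqrt(S)
  expect_lt(abs(d$dic - dic_true), 6 * se + 0.02)
  expect_lt(abs(d$pd - pd_true), 6 * se + 0.02)
})

test_that("MAE satisfies its metric identities", {
  g <- small_grid(8)
  a <- latent_field(g, runif(64))
  expect_identical(compute_mae(a, a), 0)
  b <- latent_field(g, a$values + 0.7)
  expect_equal(compute_mae(b, a), 0.7)
  expect_identical(compute_mae(a, b), compute_mae(b, a))
  expect_gte(compute_mae(a, b), 0)
  g2 <- small_grid(9)
  expect_error(compute_mae(a, latent_field(g2, runif(81))), "match")
})

test_that("approximate LCPO agrees with exact leave-one-out refits", {
  s <- tiny_scenario(seed = 63, nx = 12, range = 3, n = 20)
  fit <- fit_model(model_spec("gamma"), s$preferential,
                   control = fast_control())
  appr <- compute_lcpo(fit, method = "approximate")
  expect_true(all(appr$cpo > 0 & is.finite(appr$cpo)))
  exact <- compute_lcpo(fit, method = "exact_loo")
  expect_true(all(exact$cpo > 0 & is.finite(exact$cpo)))
  expect_lt(abs(appr$lcpo - exact$lcpo) / abs(exact$lcpo), 0.05)
})

test_that("LCPO discriminates structured from scrambled mark fits", {
  s <- tiny_scenario(seed = 64, nx = 14, range = 4, n = 60)
  fit_struct <- fit_model(model_spec("gamma", preferential = FALSE),
                          s$preferential, control = fast_control())
  scrambled <- s$preferential
  set.seed(1)
  scrambled$data$mark <- sample(scrambled$data$mark)
  fit_noise <- fit_model(model_spec("gamma", preferential = FALSE),
                         scrambled, control = fast_control())
  l_struct <- compute_lcpo(fit_struct)$lcpo
  l_noise <- compute_lcpo(fit_noise)$lcpo
  expect_lt(l_struct, l_noise)
})

test_that("scoring refuses unconverged fits and tiny samples", {
  s <- tiny_scenario(seed = 65, nx = 10, range = 3, n = 20)
  fit <- fit_model(model_spec("gamma"), s$preferential,
                   control = fast_control())
  broken <- fit
  broken$converged <- FALSE
  expect_error(compute_dic(broken), "unconverged")
  expect_error(compute_lcpo(broken), "unconverged")
  expect_error(predict_surface(broken), "unconverged")
})

test_that("draw-based DIC converges to the analytic value", {
  s <- tiny_scenario(seed = 66, nx = 10, range = 3, n = 30)
  fit <- fit_model(model_spec("gamma"), s$preferential,
                   control = fast_control())
  an <- compute_dic(fit)
  dr <- compute_dic(fit, method = "draws", S = 8000, seed = 4)
  expect_lt(abs(an$dic - dr$dic), 1.5)   # a few Monte Carlo SEs
  expect_lt(abs(an$pd - dr$pd), 1.5)
  expect_gt(an$pd, 0)
})
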