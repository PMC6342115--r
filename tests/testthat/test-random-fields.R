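# Matern machinery: closed-form correlation, SPDE precision, simulation.

test_that("Matern (nu=1) correlation matches its closed form and decays", {
  h <- matern_hyper(sigma2 = 1, range = 10)
  expect_identical(matern_correlation(0, h), 1)
  # at d = range, kappa*d = sqrt(8): corr = sqrt(8) * K_1(sqrt(8))
  expect_equal(matern_correlation(10, h), 0.1396675, tolerance = 1e-6)
  d <- seq(0.1, 40, by = 0.5)
  expect_true(all(diff(matern_correlation(d, h)) < 0))
  expect_true(all(matern_correlation(d, h) >= 0))
  expect_error(matern_correlation(-1, h), "non-negative")
})

test_that("(sigma2, range) <-> (kappa, tau) is a bijection", {
  h <- matern_hyper(sigma2 = 2.5, range = 7)
  back <- matern_hyper_from_spde(h$kappa, h$tau)
  expect_equal(back$sigma2, 2.5, tolerance = 1e-14)
  expect_equal(back$range, 7, tolerance = 1e-14)
  expect_error(matern_hyper(sigma2 = -1, range = 5))
  expect_error(matern_hyper(sigma2 = 1, range = 0))
})

test_that("SPDE precision is symmetric, positive definite, 13-nnz stencil", {
  g <- small_grid(16)
  h <- matern_hyper(1, 6)
  Q <- build_spde_precision(g, h)
  expect_equal(dim(Q), c(256L, 256L))
  expect_identical(max(abs(Q - Matrix::t(Q))), 0)
  nnz_per_row <- tabulate(methods::as(Q, "TsparseMatrix")@i + 1L, 256L)
  expect_lte(max(nnz_per_row), 13L)
  # positive definite: Cholesky succeeds
  expect_s4_class(Matrix::Cholesky(Q, LDL = FALSE), "CHMfactor")
  expect_error(spde_precision(g, matern_hyper(1, -2)))
})

test_that("dense inverse of the padded SPDE precision matches the Matern", {
  g <- small_grid(16)
  h <- matern_hyper(sigma2 = 1, range = 6)
  sp <- spde_precision(g, h, extension = 6)
  S <- solve(as.matrix(sp$Q))[sp$window, sp$window]
  v <- diag(S)
  # central 4x4 block variances within 15% of sigma2
  centre <- as.vector(outer(7:10, 7:10, function(i, j) (j - 1) * 16 + i))
  expect_true(all(abs(v[centre] - 1) < 0.15))
  # correlation one range apart vs the closed form, within 0.08
  i0 <- (8 - 1) * 16 + 8      # cell (8, 8)
  i1 <- (8 - 1) * 16 + 14     # cell (14, 8), 6 cells away
  rho_hat <- S[i0, i1] / sqrt(v[i0] * v[i1])
  expect_lt(abs(rho_hat - matern_correlation(6, h)), 0.08)
})

test_that("simulate_grf is deterministic and records its method", {
  g <- small_grid(12)
  h <- matern_hyper(1, 4)
  f1 <- simulate_grf(g, h, seed = 5)
  f2 <- simulate_grf(g, h, seed = 5)
  expect_identical(f1$values, f2$values)
  expect_identical(attr(f1, "method"), "dense")
  f3 <- simulate_grf(g, h, seed = 5, method = "gmrf")
  expect_identical(attr(f3, "method"), "gmrf")
  expect_false(identical(f1$values, simulate_grf(g, h, seed = 6)$values))
  big <- grid_geometry(80, 80)
  expect_error(simulate_grf(big, h, seed = 1, method = "dense"),
               "dense simulation limited")
  expect_identical(attr(simulate_grf(big, h, seed = 1), "method"), "gmrf")
})

test_that("simulated fields have the correct first two moments", {
  g <- small_grid(16)
  h <- matern_hyper(sigma2 = 1, range = 4)
  S <- 500
  centre <- (8 - 1) * 16 + 8
  sims <- vapply(seq_len(S), function(s)
    simulate_grf(g, h, seed = 1000 + s)$values[centre], numeric(1))
  # mean within 3 MC standard errors of 0 (per-draw sd = 1)
  expect_lt(abs(mean(sims)), 3 / sqrt(S))
  # variance within 3 MC standard errors of sigma2 = 1
  expect_lt(abs(var(sims) - 1), 3 * sqrt(2 / (S - 1)))
})

test_that("GMRF and dense simulation paths agree in their moments", {
  g <- small_grid(16)
  h <- matern_hyper(sigma2 = 1, range = 4)
  S <- 400
  centre <- (8 - 1) * 16 + 8
  dense <- vapply(seq_len(S), function(s)
    simulate_grf(g, h, seed = s, method = "dense")$values[centre],
    numeric(1))
  gmrf <- vapply(seq_len(S), function(s)
    simulate_grf(g, h, seed = 5000 + s, method = "gmrf")$values[centre],
    numeric(1))
  se_mean <- sqrt(1 / S + 1 / S)
  expect_lt(abs(mean(dense) - mean(gmrf)), 3 * se_mean)
  se_var <- sqrt(2 / (S - 1)) * sqrt(2)
  expect_lt(abs(var(dense) - var(gmrf)), 3 * se_var + 0.1)
})
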