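# Sampling designs and mark extraction.

test_that("preferentiality 0 reduces to uniform sampling", {
  g <- grid_geometry(10, 10)
  field <- simulate_grf(g, matern_hyper(1, 3), seed = 2)
  loc <- preferential_sample(field, 10000, b = 0, seed = 3)
  gof <- suppressWarnings(chisq.test(tabulate(loc$cell, 100)))
  expect_gt(gof$p.value, 0.001)
  # two-sample equivalence with the uniform sampler
  lu <- uniform_sample(g, 10000, seed = 4)
  tab <- rbind(tabulate(loc$cell, 100), tabulate(lu$cell, 100))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)
})

test_that("samplers are deterministic under a fixed seed and validate n", {
  g <- grid_geometry(10, 10)
  field <- simulate_grf(g, matern_hyper(1, 3), seed = 2)
  expect_identical(uniform_sample(g, 50, seed = 9)$cell,
                   uniform_sample(g, 50, seed = 9)$cell)
  expect_identical(preferential_sample(field, 50, b = 1, seed = 9)$cell,
                   preferential_sample(field, 50, b = 1, seed = 9)$cell)
  expect_error(uniform_sample(g, 0, seed = 1))
  expect_error(preferential_sample(field, 10, b = -1, seed = 1))
})

test_that("preferential sampling oversamples high field values", {
  g <- small_grid(16)
  field <- simulate_grf(g, matern_hyper(1, 4), seed = 11)
  gbar <- mean(field$values)
  hits <- vapply(1:100, function(r) {
    loc <- preferential_sample(field, 100, b = 1, seed = 100 + r)
    mean(field$values[loc$cell]) > gbar
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("expected sampled field value increases with preferentiality", {
  g <- small_grid(16)
  field <- simulate_grf(g, matern_hyper(1, 4), seed = 11)
  mean_at_b <- vapply(c(0, 0.5, 1, 2), function(b) {
    mean(vapply(1:200, function(r) {
      loc <- preferential_sample(field, 100, b = b, seed = 300 + r)
      mean(field$values[loc$cell])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_at_b) > 0))
})

test_that("mark extraction follows the requested observation model", {
  g <- small_grid(12)
  field <- simulate_grf(g, matern_hyper(1, 4), seed = 21)
  loc <- uniform_sample(g, 40, seed = 22)
  # noiseless gaussian extraction returns intercept + field exactly
  ms <- extract_marks(field, loc, family = "gaussian",
                      obs_params = list(sd = 0), intercept = 1.5, seed = 1)
  expect_equal(ms$data$mark, 1.5 + field$values[loc$cell])
  # gamma marks: Monte Carlo mean at one fixed cell
  cell <- 66L
  one <- loc[rep(1, 10000), ]
  one$cell <- cell
  rho <- 5
  mg <- extract_marks(field, one, family = "gamma",
                      obs_params = list(rho = rho), intercept = 0.3,
                      seed = 2)
  mu <- exp(0.3 + field$values[cell])
  se <- mu / sqrt(rho * 10000)
  expect_lt(abs(mean(mg$data$mark) - mu), 3 * se)
  expect_true(all(mg$data$mark > 0))
  # out-of-grid location and invalid parameters are rejected
  bad <- loc; bad$cell <- 10 * 144L
  expect_error(extract_marks(field, bad, family = "gamma", seed = 1),
               "outside")
  expect_error(extract_marks(field, loc, family = "gamma",
                             obs_params = list(rho = -2), seed = 1))
  expect_error(extract_marks(field, loc, family = "gamma",
                             intercept = -Inf, seed = 1))
})

test_that("scenarios are reproducible and have the study-design shape", {
  s1 <- make_scenario(seed = 77)
  s2 <- make_scenario(seed = 77)
  expect_identical(s1$field$values, s2$field$values)
  expect_identical(s1$preferential$data, s2$preferential$data)
  expect_identical(s1$uniform$data, s2$uniform$data)
  # defaults: 100 x 100 window, two sets of 100 samples on one shared field
  expect_identical(c(s1$grid$nx, s1$grid$ny), c(100L, 100L))
  expect_identical(nrow(s1$preferential$data), 100L)
  expect_identical(nrow(s1$uniform$data), 100L)
  expect_identical(s1$preferential$design$kind, "preferential")
  expect_identical(s1$uniform$design$kind, "uniform")
  expect_identical(s1$preferential$truth, s1$field)
})

test_that("preferential samples carry higher marks than uniform ones", {
  higher <- vapply(1:100, function(r) {
    s <- tiny_scenario(seed = 9000 + r, nx = 16, range = 4, n = 50)
    mean(s$preferential$data$mark) > mean(s$uniform$data$mark)
  }, logical(1))
  expect_gte(sum(higher), 90)
})

test_that("the true abundance surface is the mean-scale transform", {
  s <- tiny_scenario(seed = 5)
  ta <- true_abundance(s)
  expect_equal(ta$values, exp(s$field$values))
  expect_true(all(ta$values > 0))
})
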