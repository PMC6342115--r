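# Shared fixtures: everything is generated in code, no stored data.

small_grid <- function(n = 16) grid_geometry(n, n)

# a small, fast scenario used across fitter tests
tiny_scenario <- function(seed = 42, nx = 16, range = 4, n = 60, b = 1,
                          family = "gamma", rho = 10) {
  make_scenario(grid = grid_geometry(nx, nx),
                hyper = matern_hyper(sigma2 = 1, range = range),
                n = n, b = b, family = family,
                obs_params = if (family == "gamma") list(rho = rho)
                             else list(sd = 0.1),
                seed = seed)
}

fast_control <- function(...) psdm_control(hessian = FALSE, ...)

# finite-difference gradient of a scalar function (central differences)
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
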