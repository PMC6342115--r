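#' Sampling design descriptor
#'
#' @param kind `"preferential"` or `"uniform"`.
#' @param n Number of sampling locations (>= 1).
#' @param preferentiality Degree `b >= 0` with which the sampling intensity
#'   tracks the latent field: cells are drawn with probability proportional
#'   to `exp(b * W)`, i.e. proportional to the `b`-th power of the process
#'   intensity `exp(W)`. `b = 0` is uniform sampling; the simulation study
#'   uses `b = 1`.
#' @param with_replacement Whether a cell may be sampled more than once
#'   (default TRUE: 100 samples from 10,000 cells make exclusion
#'   immaterial, and duplicated cells are handled by the likelihood).
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(kind = c("preferential", "uniform"), n,
                          preferentiality = if (kind == "uniform") 0 else 1,
                          with_replacement = TRUE) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.numeric(preferentiality) || !is.finite(preferentiality) ||
      preferentiality < 0)
    stop("preferentiality must be finite and >= 0")
  if (kind == "uniform" && preferentiality != 0)
    stop("a uniform design has preferentiality 0")
  structure(list(kind = kind, n = n,
                 preferentiality = as.numeric(preferentiality),
                 with_replacement = isTRUE(with_replacement)),
            class = "sample_design")
}

# locations object: data.frame(cell, x, y) + design attribute
.locations <- function(grid, cells, design) {
  xy <- cell_centers(grid, cells)
  structure(data.frame(cell = as.integer(cells), x = xy[, 1], y = xy[, 2]),
            design = design, grid = grid)
}

#' Preferential sampling of grid cells
#'
#' Draws `n` cells i.i.d. with probability proportional to
#' `exp(b * W_i)` (log-sum-exp stabilised), so sampling effort concentrates
#' where the latent surface — and hence the species — is high.
#'
#' @param field A `latent_field` (the true surface `W`).
#' @param n Number of draws.
#' @param b Preferentiality degree (>= 0; 0 reduces to uniform).
#' @param seed Integer seed.
#' @param with_replacement Allow repeated cells (default TRUE).
#' @return Locations: a data.frame of `cell`, `x`, `y` with the design in
#'   `attr(, "design")`.
#' @export
preferential_sample <- function(field, n, b = 1, seed,
                                with_replacement = TRUE) {
  stopifnot(inherits(field, "latent_field"))
  if (any(!is.finite(field$values))) stop("field contains non-finite values")
  design <- sample_design("preferential", n, preferentiality = b,
                          with_replacement = with_replacement)
  w <- b * field$values
  p <- exp(w - max(w))
  p <- p / sum(p)
  set.seed(as.integer(seed))
  cells <- sample.int(n_cells(field$grid), size = n,
                      replace = with_replacement, prob = p)
  .locations(field$grid, cells, design)
}

#' Uniform (completely random) sampling of grid cells
#'
#' Equivalent in distribution to [preferential_sample()] with `b = 0`.
#'
#' @param grid A `grid_geometry`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param with_replacement Allow repeated cells (default TRUE).
#' @return Locations as in [preferential_sample()].
#' @export
uniform_sample <- function(grid, n, seed, with_replacement = TRUE) {
  stopifnot(inherits(grid, "grid_geometry"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  design <- sample_design("uniform", n, preferentiality = 0,
                          with_replacement = with_replacement)
  set.seed(as.integer(seed))
  cells <- sample.int(n_cells(grid), size = n, replace = with_replacement)
  .locations(grid, cells, design)
}

# internal constructor shared by extract_marks and read_points
new_marked_sample <- function(data, design, family, obs_params = NULL,
                              intercept = 0, truth = NULL, grid = NULL) {
  structure(list(data = data, design = design, family = family,
                 obs_params = obs_params, intercept = intercept,
                 truth = truth, grid = grid),
            class = "marked_sample")
}

#' @export
print.marked_sample <- function(x, ...) {
  cat(sprintf("<marked_sample> n=%d, family=%s, design=%s\n",
              nrow(x$data), x$family, x$design$kind))
  invisible(x)
}

#' Extract marks at sampled locations
#'
#' Simulates the observation layer: at each sampled cell the abundance mark
#' is generated from the latent surface. Under the gamma family the mark has
#' mean `exp(intercept + W(s))` and shape `rho` (`obs_params$rho`); under
#' the gaussian family the mark is `intercept + W(s)` plus N(0, sd^2) noise
#' (`obs_params$sd`, which may be 0 for noiseless extraction).
#'
#' @param field The true `latent_field`.
#' @param locations Locations from [preferential_sample()] or
#'   [uniform_sample()].
#' @param family `"gamma"` or `"gaussian"`.
#' @param obs_params List: `rho` (gamma shape > 0) or `sd` (gaussian noise
#'   sd >= 0). Defaults: `rho = 10`, `sd = 0.1`.
#' @param intercept Mark-scale intercept (log scale for gamma); default 0.
#' @param seed Integer seed.
#' @return A `marked_sample` carrying the design, observation parameters
#'   and a reference to the generating field (for truth-recovery tests).
#' @export
extract_marks <- function(field, locations, family = c("gamma", "gaussian"),
                          obs_params = NULL, intercept = 0, seed) {
  stopifnot(inherits(field, "latent_field"), is.data.frame(locations))
  family <- match.arg(family)
  cells <- locations$cell
  if (any(cells < 1L | cells > n_cells(field$grid)))
    stop("location outside the grid")
  eta <- intercept + field$values[cells]
  set.seed(as.integer(seed))
  if (family == "gamma") {
    if (is.null(obs_params)) obs_params <- list(rho = 10)
    rho <- obs_params$rho
    if (is.null(rho) || !is.finite(rho) || rho <= 0)
      stop("gamma family needs obs_params$rho > 0")
    mu <- exp(eta)
    if (any(!is.finite(mu) | mu <= 0))
      stop("gamma mean must be positive and finite")
    marks <- stats::rgamma(length(cells), shape = rho, rate = rho / mu)
  } else {
    if (is.null(obs_params)) obs_params <- list(sd = 0.1)
    sd <- obs_params$sd
    if (is.null(sd) || !is.finite(sd) || sd < 0)
      stop("gaussian family needs obs_params$sd >= 0")
    marks <- eta + stats::rnorm(length(cells), sd = sd)
  }
  df <- data.frame(x = locations$x, y = locations$y,
                   cell = cells, mark = marks)
  new_marked_sample(df, design = attr(locations, "design"), family = family,
                    obs_params = obs_params, intercept = intercept,
                    truth = field, grid = field$grid)
}

#' Generate one complete simulation scenario
#'
#' One zero-mean Matern field plus two marked samples on the same field:
#' one preferential (locations drawn with probability proportional to the
#' intensity `exp(W)^b`) and one uniform. The defaults reproduce the shape
#' of the study design: a 100 x 100 grid and two sets of 100 samples. All
#' stage seeds are derived deterministically from the master seed via
#' [derive_seed()].
#'
#' @param grid A `grid_geometry` (default 100 x 100 unit cells).
#' @param hyper A `matern_hyper` (default sigma2 = 1, range = 20% of window
#'   width).
#' @param n Samples per design (default 100).
#' @param b Preferentiality degree of the preferential design (default 1).
#' @param family Mark family, `"gamma"` (default, shape `rho = 10`) or
#'   `"gaussian"`.
#' @param obs_params Observation parameters, see [extract_marks()].
#' @param intercept Mark intercept (default 0).
#' @param seed Master integer seed.
#' @return List of class `psdm_scenario`: `field` (true `latent_field`),
#'   `preferential` and `uniform` (two `marked_sample`s), plus the
#'   configuration.
#' @export
make_scenario <- function(grid = grid_geometry(100, 100),
                          hyper = matern_hyper(sigma2 = 1,
                                               range = 0.2 * 100),
                          n = 100, b = 1,
                          family = c("gamma", "gaussian"),
                          obs_params = NULL, intercept = 0, seed) {
  family <- match.arg(family)
  if (missing(hyper) || is.null(hyper))
    hyper <- matern_hyper(sigma2 = 1,
                          range = 0.2 * grid$nx * grid$cell_size)
  field <- simulate_grf(grid, hyper, seed = derive_seed(seed, 1))
  loc_p <- preferential_sample(field, n, b = b, seed = derive_seed(seed, 2))
  loc_u <- uniform_sample(grid, n, seed = derive_seed(seed, 3))
  samp_p <- extract_marks(field, loc_p, family = family,
                          obs_params = obs_params, intercept = intercept,
                          seed = derive_seed(seed, 4))
  samp_u <- extract_marks(field, loc_u, family = family,
                          obs_params = obs_params, intercept = intercept,
                          seed = derive_seed(seed, 5))
  structure(list(field = field, preferential = samp_p, uniform = samp_u,
                 grid = grid, hyper = hyper, n = n, b = b, family = family,
                 intercept = intercept, seed = as.integer(seed)),
            class = "psdm_scenario")
}

#' True abundance surface of a scenario
#'
#' The mean-scale truth `exp(intercept + W)` for gamma-family scenarios and
#' `intercept + W` for gaussian ones; the reference surface for predictive
#' mean absolute error.
#'
#' @param scenario A `psdm_scenario`.
#' @return A `latent_field` on the scenario grid.
#' @export
true_abundance <- function(scenario) {
  stopifnot(inherits(scenario, "psdm_scenario"))
  eta <- scenario$intercept + scenario$field$values
  vals <- if (scenario$family == "gamma") exp(eta) else eta
  latent_field(scenario$grid, vals)
}
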