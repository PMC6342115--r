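---
title: "Modelling preferentially sampled abundance data with prefsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preferentially sampled abundance data with prefsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefsdm)
```

## The problem

Geostatistical species distribution models assume that where you sampled is
unrelated to what you measured. Opportunistic data — commercial fishing
hauls, bird-watching records, whale-watching sightings — violate this:
observers deliberately go where they expect the species, so locations are
*preferentially sampled* and a standard geostatistical model overestimates
abundance in the places it was never worth visiting.

`prefsdm` treats such data as a marked point pattern and fits the two
competing models:

* **Non-preferential (mark-only) model.** Marks $Y_s$ (abundance at sampled
  locations) follow an exponential-family distribution, by default

  $$Y_s \sim \mathrm{Ga}(\mu_s, \rho), \qquad
    \log \mu_s = \beta_0'' + Z_s, \qquad Z \sim N(0, Q(\kappa,\tau)^{-1}),$$

  where $Z$ is a Matérn ($\nu = 1$) Gaussian field represented by its
  sparse SPDE lattice precision $Q$ and $\rho$ is the gamma shape
  (dispersion) parameter.

* **Preferential (joint) model.** The sampling locations are additionally
  modelled as a log-Gaussian Cox process whose log-intensity *shares* the
  same field:

  $$\Lambda_s = \exp(\beta_0 + \alpha W_s), \qquad
    Y_s \sim \mathrm{Ga}(\mu_s, \rho), \qquad
    \log \mu_s = \beta_0' + W_s,$$

  with a single field $W$ and a sharing scale $\alpha$ (estimated) that
  absorbs the difference in scale between sampling intensity and abundance.
  A positive $\alpha$ says "effort concentrates where abundance is high";
  the point pattern then informs the field exactly where marks are missing,
  which is what corrects the prediction bias.

Optionally both predictors take a shared second-order random-walk (RW2)
smooth of a covariate such as bathymetry, scaled by its own $\alpha_d$
(`model_spec(share_covariate = TRUE)`). This fully shared variant is
flagged experimental: when the covariate and the field carry the same
information the point-process layer is confounded, and the fitter detects
strong collinearity between the two shared components and warns rather
than failing silently.

## Discretisation and the LGCP likelihood

Everything lives on a regular lattice (`grid_geometry`). The LGCP
likelihood uses the standard lattice approximation: cell counts are
conditionally Poisson with mean (cell area) × (cell intensity). Since the
data of interest are themselves gridded, no triangulated mesh machinery is
needed; this is the package's key numerical-fidelity decision.

The Matérn field with smoothness fixed at $\nu = 1$ (the usual default of
the SPDE approach in two dimensions) is represented by the sparse
precision

$$Q = \tau^2\,(\kappa^4 C + 2\kappa^2 G + G C^{-1} G),$$

with lumped mass matrix $C = h^2 I$ and the dimensionless 5-point-stencil
stiffness $G$; $Q$ has at most 13 nonzeros per row. The parameterisation
follows the convention `range` $= \sqrt{8\nu}/\kappa$ (the distance at
which correlation falls to about 0.1 — exactly
$\sqrt8\,K_1(\sqrt8) \approx 0.14$) and
$\sigma^2 = 1/(4\pi\kappa^2\tau^2)$. Because the lattice operator has
Neumann boundaries, variances inflate near the edge; the precision is
therefore built on a grid padded by about one correlation range and the
study window selected afterwards (`spde_precision(extension = ...)`), both
for simulation and for fitting. Two residual approximation errors remain
and are visible in the tests' tolerances: a few-percent lattice
discretisation bias in the marginal variance at moderate $\kappa h$, and a
small deficit in the implied correlation at one range (about 0.13 vs the
closed-form 0.14 at $h = \mathrm{range}/6$).

## Inference: empirical-Bayes Laplace approximation

The latent vector $u = (W_\mathrm{ext}, f, \beta\text{'s})$ is Gaussian
given the hyperparameters, so the model is a latent Gaussian model and is
fitted INLA-style, deliberately reduced to its core:

1. **Inner loop.** Newton maximisation of the joint posterior of $u$ at
   fixed hyperparameters (gradient tolerance $10^{-8}$ max-norm, at most
   50 iterations, step halving). All Hessian sparsity patterns are fixed,
   so each iteration is one numeric sparse Cholesky refactorisation with a
   cached symbolic analysis.
2. **Outer loop.** Nelder–Mead maximisation of the Laplace-approximated
   log marginal posterior of the hyperparameters
   $(2\log\kappa, \log\tau, \log\rho, \alpha, \ldots)$, started from
   deterministic initial values: range at half the window, field variance
   from the spread of the link-transformed marks, $\rho$ by moments,
   $\alpha = 1$, intercepts at link transforms of the mark mean.
3. **Summaries.** Latent marginal standard deviations come from the
   Gaussian approximation at the hyperparameter mode; hyperparameter
   uncertainty from the numeric Hessian of the Laplace objective
   (`psdm_control(hessian = TRUE)`), optionally refined by a coarse grid
   around the mode with normalised weights
   (`integrate_hyper = TRUE`). Full nested integration (CCD exploration,
   simplified Laplace corrections) is intentionally out of scope.

The test suite checks this machinery against a long-run exact MCMC
sampler of the same unnormalised posterior on a small instance, written
with its own dense-matrix density code: the latent vector is refreshed by
independence Metropolis–Hastings from the sampler's own dense Laplace
proposal (the proposal affects only efficiency; the accept ratio keeps
the chain exact), and the hyperparameters move jointly with a fresh
latent draw under an adaptive-covariance random walk — a scheme that
mixes against the (approximate) hyperparameter marginal and so avoids
the small-variance funnel a purely centered chain falls into. Where that
comparison shows daylight is informative: at cells with zero point-process
counts the latent posterior is left-skewed, so the joint mode the
Gaussian approximation reports sits slightly above the posterior mean at
a handful of cells, while the field-wide mean agreement is an order of
magnitude tighter. The corrections that would remove this (simplified or
full Laplace marginals) are exactly the machinery this package leaves
out.

### Priors

Fixed effects get zero-mean Gaussians with variance 100. The spatial
hyperparameters take either independent Gaussians on
$(2\log\kappa, \log\tau)$ centred so that the prior median range is half
the window and the prior median field sd is 1 (the vague default), or
penalised-complexity priors specified through
$P(\mathrm{range} < r_0) = p_r$ and $P(\sigma > s_0) = p_s$. The sharing
scales get standard normal priors — the natural weakly informative choice
on a dimensionless ratio of log-scale effects, made here as a design
decision since nothing stronger is implied by the model. The RW2
log-precision gets a LogGamma(4, 0.0001) prior, and the RW2 penalty is
rescaled to generalized variance 1 so that this prior means the same
thing whatever the number of knots. A tiny ridge ($10^{-6}$) makes the
intrinsic RW2 prior proper; its null space (constant + linear) is
otherwise absorbed by the intercept and the data.

## The scenario generator

`make_scenario()` reproduces the simulation design the package is built
around: a zero-mean Matérn field on a 100 × 100 grid and, on the same
field, one preferential and one uniform set of 100 samples. Preferential
locations are drawn with probability proportional to
$\Lambda_s^b = \exp(bW_s)$; the preferentiality degree `b = 1` is the
experiment's setting, `b = 0` is uniform. Cells are sampled with
replacement (100 samples from 10,000 cells make exclusion immaterial;
duplicated cells simply contribute independent mark terms and count-2
cells). Field defaults are $\sigma^2 = 1$ and range 20% of the window
width — choices documented here because the generating values are not
implied by anything else in the design; smoothness is $\nu = 1$
throughout.

Marks default to the gamma family with shape $\rho = 10$ and intercept 0,
matching the analysis likelihood; noiseless or gaussian extraction is
available because the design leaves the observation layer open. The
generator emulates the spatial structure, the preferential design and the
observation noise of real survey data; it does not emulate covariate
effects on effort, vessel behaviour, temporal structure, or detection
error, so passing tests demonstrate correctness of the method under its
own assumptions, not robustness to those failure modes.

All stage seeds derive from one master seed by a documented splitting rule
(`derive_seed`), so every stage and every replicate is independently
reproducible.

## Scoring and the simulation study

`run_simulation_study()` repeats the scenario, fits both models to either
or both designs, and scores each fit:

* **DIC** $= \bar D + p_D$, with $\bar D$ the posterior-mean deviance
  under the Gaussian approximation at the hyperparameter mode and
  $p_D = \bar D - D(\hat u)$. Under that approximation $\bar D$ is
  available in closed form for every supported family (only $E[\eta]$
  and $E[e^{\pm\eta}] = e^{\pm m + v/2}$ appear), so the default DIC is
  exact rather than a Monte Carlo estimate; the draw-based estimator is
  kept as an option and converges to the analytic value.
* **LCPO** $= -\tfrac1n \sum_i \log \mathrm{CPO}_i$, where
  $\mathrm{CPO}_i$ is the leave-one-out predictive density of mark $i$.
  The default route is the analytic Gaussian downdate: observation $i$'s
  quadratic likelihood contribution is removed from its full-data Gaussian
  marginal ($1/v_{-i} = 1/v_i - d_i^{(2)}$,
  $m_{-i} = m_i + d_i^{(1)} v_{-i}$) and the mark density integrated over
  the downdated marginal. The harmonic-mean identity
  $1/\mathrm{CPO}_i = E[1/p(y_i\mid\eta_i)]$ was evaluated and rejected:
  for gamma marks that expectation is infinite under a Gaussian
  approximation ($1/p$ grows like $\exp(\rho y e^{-\eta})$ in the lower
  tail), so its Monte Carlo estimate is unusably biased. The downdate
  agrees with exact leave-one-out refits (`method = "exact_loo"`) within
  a few percent, which the tests assert.
* **MAE**: mean absolute difference between the posterior predictive mean
  surface and the known true abundance surface $\exp(\beta + W)$ over all
  cells — possible because simulation truth is known; a held-out-points
  variant is a matter of passing a different truth surface.

DIC and LCPO are computed over the mark likelihood only, so the joint and
mark-only models are compared on the same terms; the point process enters
the scores only through its effect on the latent field. Predictive means
use the lognormal correction $E[e^\eta] = \exp(m + v/2)$, never
$\exp(m)$.

The shipped default study is scaled to one CPU: 30 replicates on a
32 × 32 grid with 100 samples per design (range 6.4 cells, gamma shape
10). At this sampling density (ten times denser than 100 points on
100 × 100) both models interpolate the marks well, which narrows the DIC
gap between them relative to sparser designs, while the LCPO and MAE
advantages of the preferential model remain large; the acceptance script
and the test suite compute the actual fractions. The full-scale
configuration (100 replicates, 100 × 100) ships as
`inst/extdata/study_full_scale.cfg` and is long-running.

## Numerical choices and degenerate inputs

* Inner Newton retries with an escalating diagonal ridge if the Hessian
  is not positive definite; hyperparameter points whose inner loop fails
  are treated as log-posterior $-\infty$ during the outer search, and the
  final mode must converge cleanly or the fit errors with diagnostics.
* Hyperparameters are box-sanitised on the natural scale (range between a
  quarter cell and 20 windows, variances within $10^{\pm 6}$, \(|\alpha| <
  25\)) to keep the derivative-free search out of absurd regions.
* Gamma marks must be strictly positive; empty samples, out-of-window
  locations, non-finite latent vectors and mismatched grids all raise
  immediate argument errors.
* Duplicate sampled cells are legitimate data: independent mark terms,
  count-2 cells in the pattern.
* A zero-variance latent posterior reduces the predictive mean to
  $\exp(m)$ exactly (the $v = 0$ limit of the lognormal correction).

## Known limitations

* Inference is empirical Bayes at the hyperparameter mode: hyperparameter
  uncertainty propagates into latent summaries only through the optional
  coarse-grid integration, and DIC/LCPO are conditioned on the modal
  hyperparameters.
* The lattice SPDE approximation carries a small variance bias at coarse
  resolutions (documented above); irregular meshes, anisotropy and
  non-stationarity are out of scope.
* Off-grid (continuous-space) sampling locations are snapped to cells;
  the binomial (presence–absence) mark family and spatiotemporal terms
  are not implemented, though the family enum leaves room.
* The fully shared covariate + field model is retained for completeness
  but is often unidentifiable, which the fitter reports as confounding.
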