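# prefsdm

Species distribution models for **preferentially sampled** abundance data.

Standard geostatistics assumes sampling locations were chosen independently
of the variable being measured. Opportunistic ecological data — commercial
fishing hauls, citizen-science bird records, whale-watching tracks — break
that assumption: observers go where they expect the species, so abundance
is systematically overestimated exactly where it is low. `prefsdm` treats
such data as a **marked point pattern** and fits, side by side:

* the **non-preferential** (mark-only) geostatistical model

  Y_s ~ Ga(mu_s, rho),  log mu_s = beta0'' + Z_s,  Z ~ N(0, Q(kappa, tau)^-1)

* the **preferential joint model**, in which the sampling locations form a
  log-Gaussian Cox process whose log-intensity shares the same latent
  Matérn field, scaled by an estimated sharing coefficient alpha:

  Lambda_s = exp(beta0 + alpha * W_s),
  Y_s ~ Ga(mu_s, rho),  log mu_s = beta0' + W_s

The field uses the SPDE lattice approximation (sparse GMRF precision,
nu = 1, range = sqrt(8)/kappa); inference is an empirical-Bayes Laplace
approximation (inner sparse-Newton over the latent field, outer
optimisation of the hyperparameter Laplace marginal, optional coarse-grid
integration). Gamma, gaussian, lognormal and poisson mark families are
supported, plus an optional shared RW2 covariate smooth (e.g. bathymetry).
Models are scored by DIC, LCPO (leave-one-out predictive density) and
predictive MAE, and a replicated simulation study quantifies how much the
preferential correction matters. For the model, priors, estimators and
design choices, see the methods vignette
(`vignettes/preferential-sampling.Rmd`).

## Worked example

Simulate one scenario — a latent Matérn field on a 32 × 32 grid with 100
locations sampled proportionally to `exp(field)` and gamma marks — then fit
both models to the *same* preferentially sampled data:

```r
library(prefsdm)

grid  <- grid_geometry(32, 32)
hyper <- matern_hyper(sigma2 = 1, range = 6.4)
scen  <- make_scenario(grid = grid, hyper = hyper, n = 100, b = 1,
                       family = "gamma", obs_params = list(rho = 10),
                       seed = 7)

fit_pref <- fit_model(model_spec("gamma", preferential = TRUE),
                      scen$preferential)
fit_geo  <- fit_model(model_spec("gamma", preferential = FALSE),
                      scen$preferential)
fit_pref
#> <psdm_fit> preferential model, gamma marks, n = 100
#>  parameter       mode
#>      range  4.7022175
#>     sigma2  0.7635563
#>        rho 12.9127153
#>      alpha  1.0764985

truth <- true_abundance(scen)
compute_mae(predict_surface(fit_pref), truth)   # 0.576
compute_mae(predict_surface(fit_geo),  truth)   # 1.148
```

The fitted sharing scale `alpha ≈ 1.08` recovers the generating
preferentiality (the data were sampled with intensity `exp(1 * W)`), and
the field range/variance land near their generating values (6.4 / 1). The
payoff is in prediction: against the known true abundance surface
`exp(W)`, the preferential model halves the mean absolute error (0.576 vs
1.148), because the pattern of *where* samples are missing tells it that
unsampled areas have low abundance, while the mark-only model extrapolates
the high values it was preferentially shown. The mark-level scores agree
(LCPO 1.726 vs 1.792, DIC 265.3 vs 272.6, lower is better).

The replicated experiment behind these single numbers:

```r
study <- run_simulation_study(R = 30, seed = 1, designs = "preferential")
study$summary   # fraction of replicates where the preferential model wins
```

A command-line wrapper covering simulation, fitting, prediction and the
study lives in `inst/cli/prefsdm` (`prefsdm study --config
inst/extdata/study_scaled.cfg --seed 7 --out results/`); the full-scale
long-running configuration is `inst/extdata/study_full_scale.cfg`. Point
tables are plain CSV (`x,y,mark`), surfaces are ESRI ASCII grids.

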