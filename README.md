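# popsync

Tools for quantifying **spatial population synchrony** — the degree to
which spatially separated populations fluctuate in parallel — from
long-term, multi-species incidence monitoring data, and for comparing
climate-driven (Moran effect) against dispersal-driven explanations of
why species differ in synchrony.

The package is aimed at population ecologists with transect-style
presence/absence survey data: repeated visits to fixed sites across
years, many species scored per visit, plus site weather, a regional
climate index (ENSO), and species trait tables.

## What it computes

1. **Synchrony index.** Per site, species and year, the fraction of day
   positives `FDP = positives / visits`; its year-over-year change
   `dFDP_t = FDP_t - FDP_{t-1}`; and per species the unweighted mean of
   pairwise Pearson correlations of `dFDP` between sites,
   after inclusion rules (sites with ≥ 8 zero-positive years dropped per
   species; species kept only at ≥ 3 sites).
2. **Climate responses.** Per species, a hierarchical Bayesian binomial
   regression with inverse-logit link
   `alpha_ij = mu_j + beta_1j winter_temp + beta_2j spring_temp +
   beta_3j winter_precip + beta_4j spring_precip + beta_5j
   summer_precip + beta_6j SSTA + beta_7j year`,
   site-level coefficients pooled through transect-wide normals
   `beta_kj ~ N(mu_beta_k, tau_beta_k)` with uninformative hyperpriors
   (`N(0, 1e-5)` precision-parameterized; `Gamma(0.1, 1e-3)` shape/rate),
   sampled by a Gibbs-within-Metropolis MCMC. Predictors are z-scored
   water-year seasonal aggregates; SSTA is the December–February mean of
   the Niño 3.4 anomaly.
3. **Factor analyses.** Maximum-likelihood factor analysis (2 factors)
   of four dispersal traits (wingspan, geographic range, diet breadth,
   elevational range) and of the five local-weather response
   coefficients (ENSO response kept standalone).
4. **Structural equation models.** A hand-rolled RAM/ML SEM engine fits
   three canned models — dispersal, climate, combined — with model
   degrees of freedom 4, 9 and 18, reporting chi-square, AIC,
   standardized paths and per-variable R²; plus migrant-exclusion and
   random-removal (drop 9 of 65, 1000×) experiments.
5. **Synthetic studies.** `generate_study()` simulates a complete study
   (default 10 sites × 65 species × 27 years, shared ENSO-like forcing,
   partially shared weather, trait tables with known factor structure)
   with full ground truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(popsync)

study <- generate_study(sim_config(n_sites = 6, n_years = 20,
                                   visits_per_year = 15), seed = 3)

res <- run_pipeline(
  study$observations, study$weather, study$ssta, study$traits,
  min_overlap_years = 10,
  mcmc = list(n_iter = 300, burn_in = 150, chains = 2),
  experiment_reps = 20, seed = 3
)

res$fits$dispersal
#> SEM fit: chi-square = 1.854 on 4 df (p = 0.763 ), AIC = 1267.941 , n = 60
#> R^2: avg_sites_occupied = 0.539, synchrony = 0.187, trend = 0.058

synchrony_distribution_summary(res$synchrony)[, 1:4]
#> # A tibble: 1 × 4
#>   n_species n_over_0.1 n_over_0.2 n_over_0.4
#>       <int>      <int>      <int>      <int>
#> 1        60         58         54         36
```

The dispersal SEM here reproduces its designed 4 degrees of freedom; the
non-significant chi-square (p = 0.76) says the model's constraints are
consistent with the synthetic covariances, and the R² line reads as "the
two trait factors and covariates explain 53.9% of the variance in the
average number of sites occupied and 18.7% of the variance in
synchrony" for this simulated assemblage. (This small simulation uses
strongly shared weather, hence the many species with index > 0.2.)

Individual stages are exported too: `compute_fdp()`,
`apply_inclusion_rules()`, `synchrony_index()`, `aggregate_seasonal()`,
`enso_winter_mean()`, `build_design()` / `run_mcmc()` /
`summarize_draws()`, `fit_ml_factors()`, `sem_spec()` / `sem_fit()`,
`exclusion_experiment()`; `tidy()`, `glance()` and `autoplot()` methods
cover the fitted objects. See the methods vignette
(`vignettes/synchrony-methods.Rmd`) for the model details and design
decisions.

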