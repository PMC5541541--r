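---
title: "Methods: quantifying and explaining spatial population synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and explaining spatial population synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(popsync)
```

popsync implements a complete analysis chain for multi-species,
multi-site incidence monitoring data: from raw per-visit detection
records to a species-level synchrony index, per-species climate
sensitivities, and structural equation models (SEMs) that weigh climate-
versus dispersal-driven explanations of synchrony. This vignette is the
package's account of the science behind each stage, the tunable
parameters, and the numerical decisions a maintainer should know about.

## The synchrony index

The primary abundance proxy is the *fraction of day positives* (FDP):
for a species at a site in a year, the number of survey visits on which
it was detected divided by the number of visits. Dividing by visits
absorbs variation in sampling effort; years with no visits produce no
record at all, which keeps "not visited" distinct from "visited, not
detected".

Synchrony operates on year-over-year changes, `dFDP(t) = FDP(t) -
FDP(t-1)`, defined only when both consecutive years were visited.
Differencing removes site-level mean differences and slow trends, so the
correlation measures shared *fluctuation*, not shared level. For each
species, Pearson's r is computed for every pair of its sites on the
years both sites have (the longer record truncated to the shared years,
applied per pair to maximize data use), and the index is the unweighted
mean of the pairwise correlations.

Two inclusion rules precede the index. A site is dropped for a species
absent (zero positives) there for eight or more years; a species must
then remain at three or more sites. "Eight or more years" is read as
*total* zero-positive years within the window — the simplest literal
reading; `consecutive = TRUE` in `apply_inclusion_rules()` switches to
the longest-run reading, since the original rule does not say which was
meant. Pairs whose overlap is shorter than `min_overlap_years` (default
24, reflecting records of at least 25 observation years) or whose
delta series has zero variance (undefined r) are dropped and logged, not
imputed as zero — zero imputation would bias the species mean toward 0.

Three species-level covariates accompany the index in the SEMs:
`abundance` (mean FDP across sites and years), `avg_sites_occupied`
(mean yearly count of sites with at least one positive visit) and
`trend` (mean dFDP, an inter-annual change measure). All are
z-standardized across the included species.

## Water-year climate predictors

Monthly site weather is aggregated to seasons on a *water year*
beginning in September of the previous calendar year, matching the
region's autumn onset of precipitation: autumn = Sep–Nov (previous
year), winter = Dec (previous) + Jan–Feb, spring = Mar–May, summer =
Jun–Aug. Seasonal temperature is the mean of the three monthly means;
seasonal precipitation the sum of the three monthly totals. Seasons with
fewer than three months (the boundary years) are flagged and excluded.

Seasonal values are z-scored *within site and variable across years*,
not pooled across sites: the predictors enter a site-indexed linear
model, and per-site scaling makes coefficients comparable across sites
that differ greatly in climatology along the elevational gradient.
Autumn variables are computed and stored but are not model predictors,
matching the model's term list. The ENSO index is the December–February
mean of the Nino 3.4 sea-surface-temperature anomaly — the seasonal peak
of ENSO — and is additionally z-scored across water years before model
fitting so that all predictors share one scale (the raw values are
retained).

`weather_redundancy_diagnostic()` reports how strongly weather is
shared across sites (mean pairwise cross-site correlation per seasonal
variable, plus a principal-component decomposition). Both readings are
reported because "average pairwise correlation of principal components"
is not a well-defined single quantity (principal components are mutually
orthogonal); nothing downstream consumes the diagnostic.

## The hierarchical climate-response model

Each species' detection series is modelled as binomial counts of day
positives out of visits, with an inverse-logit link on a linear
predictor containing winter/spring temperature, winter/spring/summer
precipitation, winter-mean SSTA, and a year term (centered and scaled
like the weather variables; the year scaling is a package decision — it
is needed for comparable Metropolis tuning across terms). Site-level
intercepts and slopes are drawn from transect-wide normal pools,

- `mu_j ~ N(mu_mu, tau_mu)`, `beta_kj ~ N(mu_beta_k, tau_beta_k)`,

with uninformative hyperpriors `N(0, 1e-5)` on the means and
`Gamma(0.1, 1e-3)` on the precisions. These are read in *sampler
convention* — Normal(mean, precision), Gamma(shape, rate) — because only
that reading makes the stated hyperpriors uninformative (variance 1e5).
The hierarchical pooling lets data-rich sites inform coefficients at
sites where a species is scarce. The species-level output is the
posterior-mean transect-wide coefficient for each of the seven terms.

The sampler is Gibbs-within-Metropolis: the transect-wide means and
precisions have exact normal-normal and gamma conjugate updates given
the site-level values; each site-level coefficient moves by random-walk
Metropolis whose per-parameter step sizes adapt toward roughly 37%
acceptance during burn-in only, so detailed balance holds for all
retained draws. Initialization is neutral (site parameters 0, hyper
means 0, precisions 1) on the z-scored predictors. Convergence is
monitored with split-chain R-hat and autocorrelation-based effective
sample size. No thinning is applied.

The full-length protocol is 2 chains of 30 000 retained iterations after
1 000 burn-in (`run_mcmc(..., n_iter = 30000, burn_in = 1000)`). The
package default is a desk-scale protocol of 2 x 5000, and the pipeline
and test suite use further reduced lengths (documented in the calls);
with conjugate hyper-updates and vectorized site sweeps the chains mix
quickly on z-scored predictors, and the reduced lengths reproduce
full-length posterior means well inside their Monte-Carlo error.

## Factor analyses

Dispersal propensity is not directly measurable, so four correlated
traits proxy it: wingspan (mm), geographical range (km^2), larval diet
breadth (host-plant genera) and elevational range (m). A
maximum-likelihood factor analysis on the correlation scale reduces them
to two factors. The same machinery reduces the five local-weather
response coefficients to two climate-sensitivity factors; the ENSO
response deliberately stays out of the factor analysis, entering the
SEMs as a standalone observed variable so regional forcing can be
compared against local weather. (The source description of the second
climate factor excludes a "summer temperature" response that is not a
model term; the package treats this as a typo for summer precipitation.)

The ML fit is written in the package: the profile Wishart criterion is
optimized over the uniquenesses by L-BFGS-B with analytic gradient, and
the loadings come from the eigen-decomposition given the uniquenesses,
with a 0.005 uniqueness floor as a Heywood guard. This is the same
algorithm `stats::factanal` uses, and agrees with it to ~1e-5 where
factanal accepts the problem; the in-package version is needed because
the dispersal case (two factors on four variables) has negative formal
testing degrees of freedom, which factanal refuses even though the
bounded optimum is well defined. Rotations: `none`, `varimax`, and
`promax` as the oblique option (no oblimin implementation is available
in the supported dependency set; promax is the standard fallback and the
rotation does not change the fitted correlation structure). Factors are
canonically oriented (largest-magnitude loading positive). Variance
explained per factor is the sum of squared structure loadings over the
number of variables; factor scores use the regression method.

On exactly uncorrelated data the ML factor solution is a ridge (a single
variable's variance can be relabelled as a "factor" without changing the
fit; factanal shows the same behaviour), so only ridge-invariant
quantities — the fitted correlation matrix, the common-variance share —
are asserted in tests for that case.

## The SEM engine

No SEM package is assumed; the engine implements the RAM (reticular
action model) formulation: directed paths and loadings in `A`, symmetric
(co)variances in `S`, implied covariance
`Sigma = F (I - A)^-1 S (I - A)^-T F^T`. Fitting minimizes the ML
discrepancy `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p` by
quasi-Newton (`nlminb`) with an analytic gradient, variance parameters
bounded below at 1e-6, heuristic marker/covariance-based starting values
and a few jittered restarts. Model chi-square is `(n-1) F_ML` (a flag
switches to `n F_ML`; the sample covariance uses `n-1` consistently),
AIC is `-2 loglik + 2q`, standard errors come from the numerically
evaluated information matrix, standardized coefficients rescale by
model-implied standard deviations (latents included), and
`R^2 = 1 - residual/implied variance` for any endogenous variable.

### The three canned models

`canned_models()` packages the dispersal, climate and combined models.
Their free-parameter sets reproduce the published model degrees of
freedom (4, 9 and 18) with the described paths; the exact path lists of
the original analyses are recoverable only from supplementary material
that is not machine-readable, so the df values and the described
structure are the binding constraints.

- *Dispersal* (8 observed variables): two correlated trait factors
  (the second excludes diet breadth), abundance as an exogenous
  covariate, a saturated recursive structure over
  `avg_sites_occupied -> synchrony -> trend`, plus two trait residual
  covariances (wingspan–elevational range, geographic range–diet
  breadth) for trait covariance the two factors do not carry. df = 4.
- *Climate* (8 observed): two correlated weather-response factors (the
  second excludes the summer-precipitation response), the ENSO response
  standalone and covarying with both factors, and a saturated recursive
  structure into synchrony and trend. df = 9 falls out exactly with no
  extra covariances.
- *Combined* (13 observed): both measurement blocks, directed links from
  the dispersal factors to the climate factors and the ENSO response,
  and the saturated structure into `avg_sites_occupied`, `synchrony`,
  `trend`. All *within-block* indicator residual covariances are free,
  so the chi-square tests exactly the cross-block structure — the
  substantive claim that traits relate to climate sensitivities and to
  synchrony only through the latents and ENSO. df = 18.

Latent scales are set by fixing each latent (residual) variance to 1
with all loadings free rather than by marker loadings: with weak factor
structure a marker-scaled latent's variance collapses toward zero while
the other loadings blow up as ratios of vanishing quantities, stalling
any optimizer; the fixed-variance convention is the same model, with the
same free-parameter count, on a smooth surface. Marker scaling remains
the default in user-written `sem_spec()` syntax (`NA*` frees a first
loading when fixed-variance scaling is wanted). Because the canned
measurement blocks are EFA-like (cross-loadings, correlated factors),
some rotation-type directions are only weakly identified; the
chi-square, df, AIC and every observed-variable R^2 are invariant to
those directions, but individual measurement-parameter standard errors
can be large on weak-factor data. A related boundary effect: when the
response factors are essentially noise (as in the synthetic generator,
whose species-level term slopes are drawn independently), a weakly
constrained latent can align itself with one outcome and push that
outcome's residual variance to its lower bound, so an R^2 near 1 for a
peripheral outcome (typically `trend`) on synthetic tables signals a
boundary solution, not real explanatory power; the chi-square and the
synchrony R^2 remain well behaved.

Both sensitivity experiments refit the same specification:
migrant-exclusion removes the flagged migratory species once;
random-removal drops `n_remove` (default 9) species uniformly, `reps`
times (default 1000; the acceptance script uses 200 for runtime — the
replicate mean stabilizes well before that), reporting the mean and a
distribution-free 95% percentile interval of the outcome R^2.
Non-converged replicates are dropped and counted.

## The synthetic-data generator

`generate_study()` produces a full study — observations, monthly
weather, SSTA, traits, and the generating truth — so every downstream
stage is testable without the original field data. Default dimensions
match the study design the package targets: 10 sites on an elevational
gradient, 65 species, 27 years, 20 visits per year, and exactly 9
migratory species.

The SSTA series is a stationary monthly AR(1) (coefficient 0.9, the
month-to-month persistence scale of ENSO indices; stationary sd 0.9 °C,
a typical Nino 3.4 anomaly spread). Site weather is a fixed seasonal
climatology (warm dry summers, wet winters) plus
`w x regional + (1 - w) x site-specific` monthly anomalies, with
`w = climate_share_weight` (default 0.8, consistent with strongly shared
regional weather); the elevational lapse is folded into the
site-specific component so `w = 1` yields literally identical sites and
`w = 0` fully independent ones, and the cross-site correlation of
seasonal values rises monotonically in `w`. Species-level true
coefficients are drawn with per-term scales (default 0.3 for weather
terms, 0.4 for SSTA, 0.2 for year, intercepts N(-1.4, 0.8) on the logit
scale) chosen so typical per-visit detection probabilities span roughly
0.05–0.6, the incidence regime of such monitoring data; site-level
coefficients spread N(mean, 0.15^2) around the species values, and
migratory species' SSTA slopes are multiplied by 3 (migrants are the
ENSO-sensitive extreme). Traits are generated from two latent factors
with documented loadings and affine-mapped to field scales, so the
factor analysis has recoverable structure. Detection counts are binomial
per site-year with probabilities from the same inverse-logit model the
analysis fits, and the seasonal predictors used for simulation are
produced by the *same* climate-prep code path the pipeline uses.

What the generator does not emulate — and hence what passing tests do
not establish about real data: within-season phenology (all visits in a
year are exchangeable), observation error and detectability differences
among species, spatially explicit dispersal (no site-to-site coupling
beyond shared climate; synchrony in the generator is purely a Moran
effect), correlated species-level responses across terms (each term's
species slope is drawn independently, so the "climate factor" structure
in real responses is absent and the canned climate/combined SEMs fit
weak factors on synthetic tables), and non-stationary trends beyond a
linear year term.

## Study window and other open points

The source material is internally inconsistent about the exact study
window (a 27-year span versus a longer collection period); the package
therefore treats the window as configuration (`n_years`, `year_start`)
and the defaults use 27 years. Whether record truncation was global or
per pair is likewise unstated; per-pair intersection is implemented
(maximizing data use and matching the pairwise computation), with the
choice isolated in `synchrony_index()`.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run everything at "desk
scale", chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error far from the tolerances: the pipeline runs on
the default 10 x 65 x 27 study with 2 x 1200 MCMC iterations per
species; slope-recovery checks use 5 sites x 50 years x 50 visits at
2 x 5000 iterations, and interval-coverage checks 50 replicate species
at 4 x 30 x 30 with 2 x 1000 iterations; the Moran-effect contrast uses
100-year series; SEM recovery uses 5000 simulated species-rows; the
random-removal experiment uses 200 replicates. Full-length settings are
single arguments away throughout.
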