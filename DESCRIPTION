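Package: popsync
Title: Spatial Population Synchrony from Long-Term Incidence Monitoring
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and explaining spatial population
    synchrony in multi-species, multi-site monitoring programmes. Computes
    fraction-of-days-positive (FDP) series from transect incidence records,
    a pairwise Pearson synchrony index on year-over-year FDP changes,
    water-year seasonal climate predictors and a winter-mean ENSO index,
    per-species hierarchical Bayesian binomial climate-response models
    fitted by a Gibbs-within-Metropolis sampler, maximum-likelihood factor
    analyses of dispersal traits and climate responses, and structural
    equation models (RAM formulation, maximum likelihood) that compare
    climate- versus dispersal-driven explanations of synchrony, including
    migrant-exclusion and random-removal experiments. A synthetic-data
    generator with known ground truth makes the full pipeline testable
    without access to the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    glue
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr
Config/testthat/edition: 3
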