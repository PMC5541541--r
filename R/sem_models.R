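# model syntax for the three canned structural equation models.
#
# latent scales are set by fixing each latent (residual) variance to 1 and
# freeing all loadings ("fixed-factor" scaling): with weakly supported
# factors this is numerically far better behaved than marker scaling,
# whose loading ratios blow up as the factor variance collapses.

dispersal_latent_model <- function() {
  "
  # measurement: two correlated dispersal-propensity factors
  Dispersal1 =~ NA*geographic_range + wingspan + diet_breadth +
                elevational_range
  Dispersal2 =~ NA*wingspan + geographic_range + elevational_range
  Dispersal1 ~~ 1*Dispersal1
  Dispersal2 ~~ 1*Dispersal2
  Dispersal1 ~~ Dispersal2
  # trait covariance not carried by the factors
  wingspan ~~ elevational_range
  geographic_range ~~ diet_breadth
  # abundance is an exogenous covariate correlated with the factors
  abundance ~~ Dispersal1
  abundance ~~ Dispersal2
  # structural part
  avg_sites_occupied ~ Dispersal1 + Dispersal2 + abundance
  synchrony ~ Dispersal1 + Dispersal2 + abundance + avg_sites_occupied
  trend ~ synchrony + avg_sites_occupied + abundance + Dispersal1 +
          Dispersal2
  "
}

climate_latent_model <- function() {
  "
  # measurement: two correlated local-weather sensitivity factors;
  # the ENSO response stays a standalone observed predictor
  Climate1 =~ NA*resp_spring_temp + resp_winter_temp + resp_winter_precip +
              resp_spring_precip + resp_summer_precip
  Climate2 =~ NA*resp_winter_temp + resp_spring_temp + resp_winter_precip +
              resp_spring_precip
  Climate1 ~~ 1*Climate1
  Climate2 ~~ 1*Climate2
  Climate1 ~~ Climate2
  resp_ssta ~~ Climate1
  resp_ssta ~~ Climate2
  # structural part
  synchrony ~ Climate1 + Climate2 + resp_ssta
  trend ~ synchrony + Climate1 + Climate2 + resp_ssta
  "
}

combined_latent_model <- function() {
  paste(
    "
  Dispersal1 =~ NA*geographic_range + wingspan + diet_breadth +
                elevational_range
  Dispersal2 =~ NA*wingspan + geographic_range + elevational_range
  Dispersal1 ~~ 1*Dispersal1
  Dispersal2 ~~ 1*Dispersal2
  Dispersal1 ~~ Dispersal2
  Climate1 =~ NA*resp_spring_temp + resp_winter_temp + resp_winter_precip +
              resp_spring_precip + resp_summer_precip
  Climate2 =~ NA*resp_winter_temp + resp_spring_temp + resp_winter_precip +
              resp_spring_precip
  Climate1 ~~ 1*Climate1
  Climate2 ~~ 1*Climate2
  # dispersal propensity feeds sensitivity to climate
  Climate1 ~ Dispersal1 + Dispersal2
  Climate2 ~ Dispersal1 + Dispersal2
  resp_ssta ~ Dispersal1 + Dispersal2
  Climate1 ~~ Climate2
  resp_ssta ~~ Climate1
  resp_ssta ~~ Climate2
  # structural part
  avg_sites_occupied ~ Dispersal1 + Dispersal2 + Climate1 + Climate2 +
                       resp_ssta
  synchrony ~ Dispersal1 + Dispersal2 + Climate1 + Climate2 + resp_ssta +
              avg_sites_occupied
  trend ~ Dispersal1 + Dispersal2 + Climate1 + Climate2 + resp_ssta +
          avg_sites_occupied + synchrony
  ",
    # within-block indicator residual covariances are left free, so the
    # chi-square tests only the cross-block structure carried by the
    # latents and the ENSO response
    paste(apply(utils::combn(c("geographic_range", "wingspan",
                               "diet_breadth", "elevational_range"), 2),
                2, paste, collapse = " ~~ "), collapse = "\n"),
    paste(apply(utils::combn(c("resp_spring_temp", "resp_winter_temp",
                               "resp_winter_precip", "resp_spring_precip",
                               "resp_summer_precip"), 2),
                2, paste, collapse = " ~~ "), collapse = "\n"),
    sep = "\n"
  )
}

scores_model <- function(which) {
  switch(which,
    dispersal = "
      avg_sites_occupied ~ dispersal1 + dispersal2 + abundance
      synchrony ~ dispersal1 + dispersal2 + abundance + avg_sites_occupied
      trend ~ synchrony + avg_sites_occupied + abundance
      dispersal1 ~~ dispersal2
      abundance ~~ dispersal1
      abundance ~~ dispersal2
    ",
    climate = "
      synchrony ~ climate1 + climate2 + resp_ssta
      trend ~ synchrony + climate1 + climate2 + resp_ssta
      climate1 ~~ climate2
      resp_ssta ~~ climate1
      resp_ssta ~~ climate2
    ",
    combined = "
      climate1 ~ dispersal1 + dispersal2
      climate2 ~ dispersal1 + dispersal2
      resp_ssta ~ dispersal1 + dispersal2
      climate1 ~~ climate2
      resp_ssta ~~ climate1
      resp_ssta ~~ climate2
      dispersal1 ~~ dispersal2
      avg_sites_occupied ~ dispersal1 + dispersal2 + climate1 + climate2 +
        resp_ssta
      synchrony ~ dispersal1 + dispersal2 + climate1 + climate2 +
        resp_ssta + avg_sites_occupied
      trend ~ synchrony + avg_sites_occupied + resp_ssta
    "
  )
}

#' Canned structural equation models
#'
#' Returns the packaged dispersal, climate or combined SEM specification.
#' The default `latent` variant carries the measurement models inside the
#' SEM, with latent scales set by fixing each latent (residual) variance
#' to 1; the `scores` variant expects factor scores (`dispersal1`,
#' `dispersal2`, `climate1`, `climate2`) entered as observed variables.
#' The free-parameter sets of the latent variants reproduce model degrees
#' of freedom 4 (dispersal), 9 (climate) and 18 (combined); in the
#' combined model all within-block indicator residual covariances are
#' free, so its chi-square tests the cross-block structure only.
#'
#' @param which `"dispersal"`, `"climate"` or `"combined"`.
#' @param variant `"latent"` or `"scores"`.
#' @return a [sem_spec()].
#' @export
#' @examples
#' sem_df(canned_models("dispersal")) # 4
#' sem_df(canned_models("climate"))   # 9
#' sem_df(canned_models("combined"))  # 18
canned_models <- function(which = c("dispersal", "climate", "combined"),
                          variant = c("latent", "scores")) {
  which <- match.arg(which)
  variant <- match.arg(variant)
  model <- if (variant == "latent") {
    switch(which,
      dispersal = dispersal_latent_model(),
      climate = climate_latent_model(),
      combined = combined_latent_model()
    )
  } else {
    scores_model(which)
  }
  sem_spec(model)
}
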