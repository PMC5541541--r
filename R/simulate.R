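#' Configuration for a synthetic monitoring study
#'
#' Defaults emulate the study design the package targets: 10 sites across
#' an elevational gradient, 65 species, 27 years of biweekly-style visits
#' (20 per year within the flight season), a shared ENSO-like regional
#' signal and partially shared local weather. `effect_scales` are the
#' standard deviations of the species-level true coefficients on the
#' z-scored seasonal predictors; defaults are chosen so typical per-visit
#' detection probabilities fall in roughly 0.05-0.6, matching
#' incidence-style data.
#'
#' @param n_sites,n_species,n_years,visits_per_year study dimensions.
#' @param year_start first observation (calendar = water) year.
#' @param climate_share_weight in `[0, 1]`; the weight of the shared
#'   regional anomaly in each site's monthly weather (1 = identical
#'   weather everywhere, 0 = fully independent sites).
#' @param ssta_ar1 monthly AR(1) coefficient of the ENSO-like SSTA series
#'   (|value| < 1).
#' @param ssta_sd stationary standard deviation of the SSTA series (deg C).
#' @param effect_scales named numeric vector of per-term standard
#'   deviations for species-level true slopes (terms `winter_temp`,
#'   `spring_temp`, `winter_precip`, `spring_precip`, `summer_precip`,
#'   `ssta`, `year`).
#' @param intercept_mean,intercept_sd species-level intercept distribution
#'   on the logit scale.
#' @param site_coef_sd spread of site-level coefficients around their
#'   species-level means.
#' @param migratory_fraction fraction of species flagged migratory (the
#'   count is `round(fraction * n_species)`, so the default gives exactly
#'   9 of 65).
#' @param migratory_ssta_boost multiplier applied to migratory species'
#'   SSTA slopes (migrants are the most ENSO-sensitive taxa).
#' @param seed default seed used by [generate_study()] when none is given.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 10, n_species = 65, n_years = 27,
                       visits_per_year = 20, year_start = 1988,
                       climate_share_weight = 0.8,
                       ssta_ar1 = 0.9, ssta_sd = 0.9,
                       effect_scales = c(
                         winter_temp = 0.3, spring_temp = 0.3,
                         winter_precip = 0.3, spring_precip = 0.3,
                         summer_precip = 0.3, ssta = 0.4, year = 0.2
                       ),
                       intercept_mean = -1.4, intercept_sd = 0.8,
                       site_coef_sd = 0.15,
                       migratory_fraction = 9 / 65,
                       migratory_ssta_boost = 3,
                       seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_species = as.integer(n_species),
    n_years = as.integer(n_years),
    visits_per_year = as.integer(visits_per_year),
    year_start = as.integer(year_start),
    climate_share_weight = climate_share_weight,
    ssta_ar1 = ssta_ar1, ssta_sd = ssta_sd,
    effect_scales = effect_scales,
    intercept_mean = intercept_mean, intercept_sd = intercept_sd,
    site_coef_sd = site_coef_sd,
    migratory_fraction = migratory_fraction,
    migratory_ssta_boost = migratory_ssta_boost,
    seed = seed
  )
  stopifnot(
    cfg$n_sites >= 1, cfg$n_species >= 1, cfg$n_years >= 1,
    cfg$visits_per_year >= 1,
    cfg$climate_share_weight >= 0, cfg$climate_share_weight <= 1,
    abs(cfg$ssta_ar1) < 1,
    cfg$migratory_fraction >= 0, cfg$migratory_fraction <= 1,
    cfg$site_coef_sd >= 0,
    all(model_terms() %in% names(cfg$effect_scales))
  )
  class(cfg) <- "sim_config"
  cfg
}

# the seven regression terms of the climate-response model, in order
model_terms <- function() {
  c("winter_temp", "spring_temp", "winter_precip", "spring_precip",
    "summer_precip", "ssta", "year")
}

sim_site_ids <- function(config) {
  sprintf("S%02d", seq_len(config$n_sites))
}

sim_species_ids <- function(config) {
  sprintf("sp%03d", seq_len(config$n_species))
}

sim_site_elevations <- function(config) {
  if (config$n_sites == 1) {
    return(0)
  }
  seq(0, 2750, length.out = config$n_sites)
}

#' Simulate monthly weather and an ENSO-like SSTA series
#'
#' The SSTA series is a stationary monthly AR(1). Each site's monthly
#' weather anomaly is `climate_share_weight` times a shared regional
#' anomaly plus `1 - climate_share_weight` times independent site noise,
#' added to a fixed seasonal climatology; the elevational mean shift is
#' folded into the site-specific component so that the share weight
#' interpolates cleanly from fully shared (identical sites) to fully
#' independent weather. The monthly span covers September of the year
#' before `year_start` through August of the final observation year, so
#' every observation water year has complete seasons. Deterministic under
#' `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list with `weather` (monthly site weather tibble) and `ssta`
#'   (monthly SSTA tibble).
#' @export
simulate_environment <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, "environment"), {
    y0 <- config$year_start
    y1 <- config$year_start + config$n_years - 1L
    months <- expand_grid(year = (y0 - 1L):y1, month = 1:12) |>
      filter(!(.data$year == y0 - 1L & .data$month < 9L)) |>
      filter(!(.data$year == y1 & .data$month > 8L))
    n_m <- nrow(months)

    phi <- config$ssta_ar1
    innov_sd <- config$ssta_sd * sqrt(1 - phi^2)
    x <- numeric(n_m)
    x[1] <- rnorm(1, 0, config$ssta_sd)
    eps <- rnorm(n_m - 1, 0, innov_sd)
    for (t in 2:n_m) x[t] <- phi * x[t - 1] + eps[t - 1]
    ssta <- tibble(year = months$year, month = months$month, ssta = x)

    w <- config$climate_share_weight
    temp_clim <- 15 + 8 * cos(2 * pi * (months$month - 7) / 12)
    precip_clim <- 60 + 55 * cos(2 * pi * (months$month - 1) / 12)
    reg_t <- rnorm(n_m, 0, 1.6)
    reg_p <- rnorm(n_m, 0, 0.35)
    elev <- sim_site_elevations(config)
    weather <- map(seq_len(config$n_sites), function(j) {
      site_t <- rnorm(n_m, 0, 1.6)
      site_p <- rnorm(n_m, 0, 0.35)
      lapse <- -6.5 * elev[j] / 1000
      tibble(
        site_id = sim_site_ids(config)[j],
        year = months$year, month = months$month,
        tmean = temp_clim + (1 - w) * lapse + w * reg_t + (1 - w) * site_t,
        precip = pmax(0, precip_clim *
                        (1 + w * reg_p + (1 - w) * site_p))
      )
    }) |>
      list_rbind()
    list(weather = weather, ssta = ssta)
  })
}

# documented trait factor structure: two latent factors, "mobility"
# (geographic range, diet breadth, elevational range) and "size"
# (wingspan, geographic range, elevational range)
trait_loadings <- function() {
  l <- rbind(
    wingspan = c(0.25, 0.80),
    geographic_range = c(0.70, 0.45),
    diet_breadth = c(0.75, 0.00),
    elevational_range = c(0.60, 0.30)
  )
  colnames(l) <- c("mobility", "size")
  l
}

trait_scales <- function() {
  tibble(
    trait = rownames(trait_loadings()),
    center = c(45, 4.5e6, 10, 1600),
    scale = c(8, 8e5, 3, 280)
  )
}

#' Simulate species-level ground truth and a trait table
#'
#' Species-level true slopes are drawn with the configured effect scales;
#' site-level coefficients are Normal around the species means with
#' standard deviation `site_coef_sd`. Migratory species (an exact count of
#' `round(migratory_fraction * n_species)`) have their SSTA slope
#' multiplied by `migratory_ssta_boost`. Traits are generated from two
#' latent factors with the documented loadings (see
#' `popsync:::trait_loadings`), then mapped to field scales by affine
#' transforms, so a 2-factor analysis has recoverable structure.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list with `truth` (list: `species`, `site`, `factors`,
#'   `loadings`, `uniquenesses`) and `traits` (tibble).
#' @export
simulate_species <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, "species"), {
    n <- config$n_species
    ids <- sim_species_ids(config)
    lam <- trait_loadings()
    psi <- pmax(1 - rowSums(lam^2), 0.005)
    f <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, colnames(lam)))
    z <- f %*% t(lam) +
      matrix(rnorm(n * 4), n, 4) %*% diag(sqrt(psi))
    sc <- trait_scales()
    traits_num <- sweep(sweep(z, 2, sc$scale, `*`), 2, sc$center, `+`)
    n_mig <- round(config$migratory_fraction * n)
    migratory <- rep(FALSE, n)
    if (n_mig > 0) migratory[sample.int(n, n_mig)] <- TRUE
    traits <- tibble(
      species_id = ids,
      wingspan = pmax(traits_num[, "wingspan"], 1),
      geographic_range = pmax(traits_num[, "geographic_range"], 1e4),
      diet_breadth = pmax(round(traits_num[, "diet_breadth"]), 1),
      elevational_range = pmax(traits_num[, "elevational_range"], 10),
      migratory = migratory
    )

    terms <- model_terms()
    mu_mu <- rnorm(n, config$intercept_mean, config$intercept_sd)
    mu_beta <- sapply(terms, function(k) {
      rnorm(n, 0, config$effect_scales[[k]])
    })
    mu_beta <- matrix(mu_beta, nrow = n,
                      dimnames = list(ids, terms))
    mu_beta[migratory, "ssta"] <-
      mu_beta[migratory, "ssta"] * config$migratory_ssta_boost
    species <- as_tibble(mu_beta, .name_repair = "minimal") |>
      setNames(paste0("beta_", terms)) |>
      mutate(species_id = ids, migratory = migratory, mu = mu_mu,
             .before = 1)

    sites <- sim_site_ids(config)
    site_tbl <- expand_grid(species_id = ids, site_id = sites)
    m <- nrow(site_tbl)
    ix <- match(site_tbl$species_id, ids)
    site_tbl$mu <- rnorm(m, mu_mu[ix], config$site_coef_sd)
    for (k in terms) {
      site_tbl[[paste0("beta_", k)]] <-
        rnorm(m, mu_beta[ix, k], config$site_coef_sd)
    }
    list(
      truth = list(species = species, site = site_tbl,
                   factors = as_tibble(f) |> mutate(species_id = ids),
                   loadings = lam, uniquenesses = psi),
      traits = traits
    )
  })
}

# z-scored seasonal predictors per site x water year, built through the
# same climate_prep code path the analysis pipeline uses
sim_predictors <- function(environment, config) {
  seasonal <- aggregate_seasonal(environment$weather)
  enso <- enso_winter_mean(environment$ssta)
  years <- config$year_start:(config$year_start + config$n_years - 1L)
  x <- seasonal |>
    filter(.data$water_year %in% years,
           .data$variable %in% model_terms()) |>
    select("site_id", "water_year", "variable", "z") |>
    pivot_wider(names_from = "variable", values_from = "z") |>
    left_join(select(enso, "water_year", ssta = "ssta_z"),
              by = "water_year") |>
    mutate(year = zscore(.data$water_year))
  if (anyNA(x[, model_terms()])) {
    abort("missing predictor for some site x year",
          class = "popsync_error_generation")
  }
  x
}

#' Simulate a visit-level observation table from ground truth
#'
#' Per site, water year and species, the linear predictor is evaluated on
#' the z-scored seasonal predictors (computed through the same climate-prep
#' code path used by the analysis), the number of detected visits is drawn
#' Binomial(`visits_per_year`, inverse-logit of the predictor) and
#' expanded to per-visit detection rows. Deterministic under `seed`.
#'
#' @param environment output of [simulate_environment()].
#' @param truth `truth` element from [simulate_species()].
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return visit-level observation tibble (see [read_observations()]).
#' @export
simulate_observations <- function(environment, truth, config,
                                  seed = config$seed) {
  with_seed(derive_seed(seed, "observations"), {
    x <- sim_predictors(environment, config)
    terms <- model_terms()
    site <- truth$site
    key <- x |>
      select("site_id", "water_year") |>
      mutate(row = dplyr::row_number())
    xm <- as.matrix(x[, terms])
    grid <- expand_grid(
      species_site = seq_len(nrow(site)),
      row = seq_len(nrow(x))
    ) |>
      filter(site$site_id[.data$species_site] == x$site_id[.data$row])
    alpha <- site$mu[grid$species_site] +
      rowSums(xm[grid$row, , drop = FALSE] *
                as.matrix(site[grid$species_site,
                               paste0("beta_", terms)]))
    p <- plogis(alpha)
    pos <- rbinom(length(p), config$visits_per_year, p)
    per_cell <- tibble(
      site_id = site$site_id[grid$species_site],
      species_id = site$species_id[grid$species_site],
      year = x$water_year[grid$row],
      positives = pos
    )
    # expand to per-visit rows; which visits are positive is arbitrary for
    # all downstream statistics, so the first `positives` visits are used
    per_cell |>
      expand_grid(visit_index = seq_len(config$visits_per_year)) |>
      mutate(detected = as.integer(.data$visit_index <= .data$positives)) |>
      select("site_id", "year", "visit_index", "species_id", "detected") |>
      arrange(.data$site_id, .data$species_id, .data$year,
              .data$visit_index)
  })
}

#' Generate a complete self-consistent synthetic study
#'
#' One call yields observations, monthly weather, SSTA, traits and the
#' generating ground truth. Identical seeds give identical outputs.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to the config seed).
#' @return list with `observations`, `weather`, `ssta`, `traits`, `truth`,
#'   and `config`.
#' @export
generate_study <- function(config = sim_config(), seed = config$seed) {
  env <- simulate_environment(config, seed = seed)
  sp <- simulate_species(config, seed = seed)
  obs <- simulate_observations(env, sp$truth, config, seed = seed)
  list(observations = obs, weather = env$weather, ssta = env$ssta,
       traits = sp$traits, truth = sp$truth, config = config)
}
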