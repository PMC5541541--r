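# shared fixtures, built in code and memoized across test files

.popsync_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .popsync_cache)) {
    assign(key, force(expr), envir = .popsync_cache)
  }
  get(key, envir = .popsync_cache)
}

# a small but complete synthetic study used by several test files
shared_study <- function() {
  memo("study", generate_study(
    sim_config(n_sites = 6, n_species = 30, n_years = 20,
               visits_per_year = 15),
    seed = 101
  ))
}

# species table assembled from the shared study with a fast MCMC pass
shared_species_table <- function() {
  memo("species_table", {
    st <- shared_study()
    fdp <- compute_fdp(st$observations)
    incl <- apply_inclusion_rules(fdp)
    delta <- compute_delta(incl$fdp)
    sync <- synchrony_index(delta, min_overlap_years = 10)
    covs <- species_covariates(incl$fdp, delta)
    seasonal <- aggregate_seasonal(st$weather)
    enso <- enso_winter_mean(st$ssta)
    responses <- fit_species_responses(incl$fdp, seasonal, enso,
                                       n_iter = 250, burn_in = 150,
                                       chains = 2, seed = 101)
    tab <- assemble_species_table(sync, covs, responses, st$traits)
    popsync:::standardize_species_table(tab)
  })
}

# build a compact visit-level observation tibble from per-(site, year)
# detection patterns: patterns[[site]][[as.character(year)]] is an integer
# 0/1 vector over visits for each species column
make_obs <- function(df) {
  stopifnot(all(c("site_id", "year", "visit_index", "species_id",
                  "detected") %in% names(df)))
  tibble::as_tibble(df)
}

# observations where species' detections per site-year are given as counts
# out of n_visits
obs_from_counts <- function(counts, n_visits) {
  purrr::pmap(counts, function(site_id, year, species_id, k) {
    tibble::tibble(
      site_id = site_id, year = year, visit_index = seq_len(n_visits),
      species_id = species_id,
      detected = as.integer(seq_len(n_visits) <= k)
    )
  }) |>
    purrr::list_rbind()
}

# a species-level ground truth with fixed transect-wide coefficients,
# site-level spread site_sd, for the recovery experiments
make_truth <- function(config, mu = -0.5, betas = c(), site_sd = 0.15,
                       seed = 1) {
  terms <- popsync:::model_terms()
  mb <- setNames(rep(0, length(terms)), terms)
  mb[names(betas)] <- betas
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  withr::with_seed(seed, {
    site_tbl <- tidyr::expand_grid(species_id = "sp001", site_id = sites)
    site_tbl$mu <- rnorm(config$n_sites, mu, site_sd)
    for (k in terms) {
      site_tbl[[paste0("beta_", k)]] <-
        rnorm(config$n_sites, mb[[k]], site_sd)
    }
    list(
      species = tibble::tibble(species_id = "sp001", migratory = FALSE,
                               mu = mu,
                               !!!setNames(as.list(mb),
                                           paste0("beta_", terms))),
      site = site_tbl
    )
  })
}
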