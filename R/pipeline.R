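#' Assemble the species-level analysis table
#'
#' Inner-joins the synchrony indices, z-scored covariates, posterior-mean
#' climate responses and dispersal traits on species; species missing any
#' component are logged and excluded.
#'
#' @param synchrony tibble from [synchrony_index()].
#' @param covariates tibble from [species_covariates()].
#' @param responses tibble from [fit_species_responses()].
#' @param traits tibble as from [read_traits()].
#' @return tibble with one row per fully characterized species; attribute
#'   `"excluded"` lists species dropped and the component they lacked.
#' @export
assemble_species_table <- function(synchrony, covariates, responses,
                                   traits) {
  parts <- list(
    synchrony = filter(synchrony, is.finite(.data$index)),
    covariates = covariates, responses = responses, traits = traits
  )
  ids <- map(parts, function(p) unique(p$species_id))
  common <- Reduce(intersect, ids)
  if (!length(common)) {
    stop_validation("no species present in all components")
  }
  excluded <- imap(parts, function(p, nm) {
    missing <- setdiff(unique(unlist(ids)), unique(p$species_id))
    if (length(missing)) {
      tibble(species_id = missing, missing_component = nm)
    }
  }) |>
    purrr::compact() |>
    list_rbind()
  out <- parts$synchrony |>
    select("species_id", synchrony = "index") |>
    inner_join(select(parts$covariates, "species_id",
                      abundance = "abundance_z",
                      avg_sites_occupied = "avg_sites_occupied_z",
                      trend = "trend_z"),
               by = "species_id") |>
    inner_join(parts$responses, by = "species_id") |>
    inner_join(parts$traits, by = "species_id") |>
    arrange(.data$species_id)
  structure(out, excluded = excluded)
}

# z-score the numeric analysis columns of a species table (the SEM fit is
# invariant to this, but it conditions the optimization)
standardize_species_table <- function(tbl) {
  num <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                 "species_id")
  for (v in num) tbl[[v]] <- zscore(tbl[[v]])
  tbl
}

#' Run the full synchrony analysis pipeline
#'
#' Sequences the whole analysis: FDP and inclusion rules, delta-FDP and
#' the synchrony index, seasonal climate and ENSO preparation, per-species
#' hierarchical Bayesian climate responses, the two factor analyses
#' (dispersal traits and the five local-weather responses; the ENSO
#' response stays out of the factor analysis), the three structural
#' equation models, and the migrant-exclusion plus random-removal
#' experiments. Identical inputs and seed give identical results.
#'
#' @param observations,weather,ssta,traits input tibbles (see the
#'   `read_*` readers), e.g. the elements of [generate_study()].
#' @param min_sites,absence_years inclusion-rule thresholds
#'   (see [apply_inclusion_rules()]).
#' @param min_overlap_years pair-overlap threshold for
#'   [synchrony_index()].
#' @param mcmc list of sampler settings: `n_iter`, `burn_in`, `chains`.
#' @param sem_variant `"latent"` or `"scores"` (see [canned_models()]).
#' @param experiment_reps random-removal replicates per model.
#' @param experiment_n_remove species removed per replicate.
#' @param seed master seed propagated to every stochastic stage.
#' @param out_dir optional directory; when given, writes `synchrony.csv`,
#'   `responses.csv`, `species_table.csv`, `exclusions.csv` and
#'   `report.json`.
#' @return list with `synchrony`, `covariates`, `responses`,
#'   `species_table`, `factors` (dispersal and climate solutions), `fits`
#'   (three `sem_fit`s), `experiments`, `report` (plain-list summary).
#' @export
run_pipeline <- function(observations, weather, ssta, traits,
                         min_sites = 3, absence_years = 8,
                         min_overlap_years = 24,
                         mcmc = list(n_iter = 1500, burn_in = 500,
                                     chains = 2),
                         sem_variant = "latent",
                         experiment_reps = 200, experiment_n_remove = 9,
                         seed = 1L, out_dir = NULL) {
  fdp <- compute_fdp(observations)
  incl <- apply_inclusion_rules(fdp, min_sites = min_sites,
                                absence_years = absence_years)
  if (nrow(incl$fdp) == 0) {
    abort("no species survive the inclusion rules",
          class = "popsync_error_empty")
  }
  delta <- compute_delta(incl$fdp)
  sync <- synchrony_index(delta, min_overlap_years = min_overlap_years)
  if (!any(is.finite(sync$index))) {
    abort("no species has a defined synchrony index",
          class = "popsync_error_empty")
  }
  covs <- species_covariates(incl$fdp, delta)

  seasonal <- aggregate_seasonal(weather)
  enso <- enso_winter_mean(ssta)
  responses <- fit_species_responses(
    incl$fdp, seasonal, enso,
    n_iter = mcmc$n_iter, burn_in = mcmc$burn_in, chains = mcmc$chains,
    seed = seed
  )

  species_table <- assemble_species_table(sync, covs, responses, traits)
  std_table <- standardize_species_table(species_table)

  fa_dispersal <- fit_ml_factors(
    std_table,
    cols = c("wingspan", "geographic_range", "diet_breadth",
             "elevational_range"),
    k = 2
  )
  fa_climate <- fit_ml_factors(
    std_table,
    cols = paste0("resp_", c("spring_temp", "winter_temp",
                             "winter_precip", "spring_precip",
                             "summer_precip")),
    k = 2
  )
  if (sem_variant == "scores") {
    sc_d <- factor_scores(fa_dispersal, std_table)
    sc_c <- factor_scores(fa_climate, std_table)
    std_table$dispersal1 <- sc_d[, 1]
    std_table$dispersal2 <- sc_d[, 2]
    std_table$climate1 <- sc_c[, 1]
    std_table$climate2 <- sc_c[, 2]
  }

  models <- c("dispersal", "climate", "combined")
  fits <- map(setNames(models, models), function(m) {
    sem_fit(canned_models(m, variant = sem_variant), std_table)
  })
  experiments <- list()
  for (m in models) {
    spec_m <- canned_models(m, variant = sem_variant)
    experiments[[paste0(m, "_migrants")]] <- exclusion_experiment(
      spec_m, std_table, mode = "migrants"
    )
    experiments[[paste0(m, "_random")]] <- exclusion_experiment(
      spec_m, std_table, mode = "random", n_remove = experiment_n_remove,
      reps = experiment_reps, seed = derive_seed(seed, "removal", m)
    )
  }

  report <- list(
    schema_version = "1.0",
    n_species = nrow(species_table),
    synchrony = as.list(synchrony_distribution_summary(sync)),
    factor_variance = list(
      dispersal = unname(variance_explained(fa_dispersal)),
      climate = unname(variance_explained(fa_climate))
    ),
    sem = map(fits, function(f) {
      list(chisq = f$chisq, df = f$df, p = f$pvalue, aic = f$aic,
           r2_synchrony = sem_r2(f, "synchrony"),
           r2_trend = sem_r2(f, "trend"),
           r2_avg_sites = tryCatch(sem_r2(f, "avg_sites_occupied"),
                                   error = function(e) NULL))
    }),
    experiments = map(experiments, function(e) {
      list(mode = e$mode, mean_r2 = e$mean,
           ci = as.numeric(e$ci), n_refit = e$n_refit,
           n_failed = e$n_failed)
    }),
    seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(as_tibble(sync), file.path(out_dir, "synchrony.csv"))
    write_table(responses, file.path(out_dir, "responses.csv"))
    write_table(species_table, file.path(out_dir, "species_table.csv"))
    if (nrow(incl$exclusions)) {
      write_table(incl$exclusions, file.path(out_dir, "exclusions.csv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(
    synchrony = sync, covariates = covs, responses = responses,
    species_table = species_table,
    factors = list(dispersal = fa_dispersal, climate = fa_climate),
    fits = fits, experiments = experiments, report = report,
    exclusions = incl$exclusions
  )
}
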