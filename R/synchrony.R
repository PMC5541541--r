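#' Fractional day positives (FDP) per site, species and year
#'
#' For each site and year, the number of visits is the count of distinct
#' visit indices recorded at that site; FDP for a species is the number of
#' those visits on which it was detected, divided by the number of visits --
#' an incidence-based abundance proxy that accounts for variation in
#' sampling effort. Species in the configured species list that were never
#' recorded at a site still get records (with zero positives) for every
#' visited year. Years with no visits yield no record at all, which keeps
#' "not visited" distinct from "visited, not detected".
#'
#' @param observations visit-level tibble as from [read_observations()].
#' @param species optional character vector of species to tabulate;
#'   defaults to all species present in `observations`.
#' @return tibble with `site_id`, `species_id`, `year`, `visits`,
#'   `positives`, `fdp`.
#' @export
compute_fdp <- function(observations, species = NULL) {
  species <- species %||% sort(unique(observations$species_id))
  effort <- observations |>
    distinct(.data$site_id, .data$year, .data$visit_index) |>
    count(.data$site_id, .data$year, name = "visits")
  pos <- observations |>
    filter(.data$species_id %in% species) |>
    group_by(.data$site_id, .data$year, .data$species_id) |>
    summarise(positives = sum(.data$detected), .groups = "drop")
  effort |>
    expand_grid(species_id = species) |>
    left_join(pos, by = c("site_id", "year", "species_id")) |>
    mutate(positives = dplyr::coalesce(.data$positives, 0L),
           fdp = .data$positives / .data$visits) |>
    select("site_id", "species_id", "year", "visits", "positives", "fdp") |>
    arrange(.data$site_id, .data$species_id, .data$year)
}

#' Year-over-year change in FDP
#'
#' The previous year's FDP is subtracted from the current year's FDP.
#' A change is defined only when both consecutive calendar years have
#' visits at the site; gaps in the record yield no value.
#'
#' @param fdp tibble from [compute_fdp()].
#' @return tibble with `site_id`, `species_id`, `year` (the later year of
#'   the pair) and `delta_fdp` in `[-1, 1]`.
#' @export
compute_delta <- function(fdp) {
  fdp |>
    group_by(.data$site_id, .data$species_id) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(delta_fdp = ifelse(.data$year - lag(.data$year) == 1L,
                              .data$fdp - lag(.data$fdp), NA_real_)) |>
    ungroup() |>
    filter(!is.na(.data$delta_fdp)) |>
    select("site_id", "species_id", "year", "delta_fdp")
}

#' Apply the site- and species-level inclusion rules
#'
#' A site is dropped for a species when the species was absent (zero
#' positives) there for at least `absence_years` years; by default absence
#' years are counted in total across the analyzed window, with
#' `consecutive = TRUE` switching to the longest consecutive run. A species
#' is then dropped entirely if it remains at fewer than `min_sites` sites.
#' Every exclusion is logged with the rule that triggered it.
#'
#' @param fdp tibble from [compute_fdp()].
#' @param min_sites minimum number of sites for a species to be analyzed.
#' @param absence_years number of zero-positive years at which a site is
#'   dropped for a species.
#' @param consecutive count absence years as the longest consecutive run
#'   instead of the total.
#' @return list with `fdp` (filtered tibble) and `exclusions` (tibble with
#'   `species_id`, `site_id` (NA for species-level exclusions), `rule`,
#'   `detail`).
#' @export
apply_inclusion_rules <- function(fdp, min_sites = 3, absence_years = 8,
                                  consecutive = FALSE) {
  absence <- fdp |>
    group_by(.data$species_id, .data$site_id) |>
    summarise(n_absent = if (consecutive) {
      r <- rle(.data$positives[order(.data$year)] == 0L)
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    } else {
      sum(.data$positives == 0L)
    }, .groups = "drop")
  dropped_sites <- filter(absence, .data$n_absent >= absence_years)
  log1 <- tibble(
    species_id = dropped_sites$species_id,
    site_id = dropped_sites$site_id,
    rule = "site_absence",
    detail = glue::glue(
      "{dropped_sites$n_absent} zero-positive years >= {absence_years}"
    )
  )
  kept <- anti_join(fdp, dropped_sites, by = c("species_id", "site_id"))
  sites_left <- count(distinct(kept, .data$species_id, .data$site_id),
                      .data$species_id, name = "n_sites")
  few <- filter(sites_left, .data$n_sites < min_sites)
  missing_entirely <- setdiff(unique(fdp$species_id), sites_left$species_id)
  log2 <- tibble(
    species_id = c(few$species_id, missing_entirely),
    site_id = NA_character_,
    rule = "min_sites",
    detail = glue::glue(
      "{c(few$n_sites, rep(0L, length(missing_entirely)))} ",
      "site(s) remaining < {min_sites}"
    )
  )
  kept <- filter(kept, !.data$species_id %in% log2$species_id)
  list(fdp = kept, exclusions = bind_rows(log1, log2))
}

pairwise_pearson <- function(delta_wide, min_overlap_years) {
  sites <- setdiff(names(delta_wide), "year")
  if (length(sites) < 2) {
    return(tibble(site_a = character(), site_b = character(),
                  r = numeric(), n_years = integer(), dropped = character()))
  }
  pairs <- utils::combn(sites, 2, simplify = FALSE)
  map(pairs, function(p) {
    x <- delta_wide[[p[1]]]
    y <- delta_wide[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    dropped <- NA_character_
    r <- NA_real_
    if (n < max(2L, min_overlap_years)) {
      dropped <- glue::glue("overlap {n} < min_overlap_years")
    } else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      dropped <- "zero-variance delta series"
    } else {
      r <- cor(x[ok], y[ok])
    }
    tibble(site_a = p[1], site_b = p[2], r = r, n_years = n,
           dropped = dropped)
  }) |>
    list_rbind()
}

#' Species-level synchrony index
#'
#' For each species and each pair of its sites, the two delta-FDP series are
#' aligned on their shared years (the longer record truncated to the years
#' both sites have), Pearson's r is computed, and the species index is the
#' unweighted mean of the pairwise correlations. Pairs whose overlap is
#' shorter than `min_overlap_years`, or whose delta series has zero
#' variance (r undefined), are dropped and logged. Species with no valid
#' pair get an `NA` index and are flagged.
#'
#' @param delta tibble from [compute_delta()] (after inclusion rules).
#' @param min_overlap_years minimum shared delta-years for a pair to count.
#'   The default reflects records of at least 25 observation years.
#' @return tibble with `species_id`, `index`, `n_sites`, `n_pairs`,
#'   `mean_overlap_years`, plus attribute `"pair_log"` holding the
#'   per-pair detail (including dropped pairs and why).
#' @export
synchrony_index <- function(delta, min_overlap_years = 24) {
  by_species <- delta |>
    group_by(.data$species_id) |>
    group_map(function(d, key) {
      wide <- pivot_wider(d[, c("year", "site_id", "delta_fdp")],
                          names_from = "site_id",
                          values_from = "delta_fdp")
      pr <- pairwise_pearson(wide, min_overlap_years)
      pr$species_id <- key$species_id
      pr
    })
  pair_log <- list_rbind(by_species)
  idx <- pair_log |>
    group_by(.data$species_id) |>
    summarise(
      index = if (any(is.finite(.data$r))) mean(.data$r[is.finite(.data$r)])
              else NA_real_,
      n_sites = dplyr::n_distinct(c(.data$site_a, .data$site_b)),
      n_pairs = sum(is.finite(.data$r)),
      mean_overlap_years = mean(.data$n_years[is.finite(.data$r)]),
      .groups = "drop"
    )
  structure(idx, pair_log = pair_log)
}

#' Species-level covariates for structural equation models
#'
#' Computes, per species: `abundance` (mean FDP across sites and years),
#' `avg_sites_occupied` (mean yearly count of sites with at least one
#' positive visit) and `trend` (mean delta-FDP across sites and years, a
#' measure of inter-annual population change). Each is then z-standardized
#' across the included species (`*_z` columns).
#'
#' @param fdp tibble from [compute_fdp()] after inclusion rules.
#' @param delta tibble from [compute_delta()] on the same filtered series.
#' @return tibble with raw and z-scored covariates per species.
#' @export
species_covariates <- function(fdp, delta) {
  if (dplyr::n_distinct(fdp$species_id) < 2) {
    abort("z-scoring needs at least two species",
          class = "popsync_error_degenerate")
  }
  ab <- fdp |>
    group_by(.data$species_id) |>
    summarise(abundance = mean(.data$fdp), .groups = "drop")
  occ <- fdp |>
    group_by(.data$species_id, .data$year) |>
    summarise(n_occ = sum(.data$positives >= 1L), .groups = "drop") |>
    group_by(.data$species_id) |>
    summarise(avg_sites_occupied = mean(.data$n_occ), .groups = "drop")
  tr <- delta |>
    group_by(.data$species_id) |>
    summarise(trend = mean(.data$delta_fdp), .groups = "drop")
  out <- ab |>
    left_join(occ, by = "species_id") |>
    left_join(tr, by = "species_id")
  out |>
    mutate(
      abundance_z = zscore(.data$abundance),
      avg_sites_occupied_z = zscore(.data$avg_sites_occupied),
      trend_z = zscore(.data$trend)
    )
}

#' Distributional summary of species synchrony indices
#'
#' Tallies how many species exceed conventional synchrony cut points (0.1
#' weakly synchronized, 0.2 fairly synchronized, 0.4 highly synchronized),
#' how many fluctuate asynchronously (negative index) and the minimum
#' index.
#'
#' @param index tibble from [synchrony_index()] (or any table with a
#'   numeric `index` column).
#' @return one-row tibble with `n_species`, `n_over_0.1`, `n_over_0.2`,
#'   `n_over_0.4`, `n_negative`, `min_index`, `mean_index`.
#' @export
synchrony_distribution_summary <- function(index) {
  x <- index$index[is.finite(index$index)]
  tibble(
    n_species = length(x),
    n_over_0.1 = sum(x > 0.1),
    n_over_0.2 = sum(x > 0.2),
    n_over_0.4 = sum(x > 0.4),
    n_negative = sum(x < 0),
    min_index = min(x),
    mean_index = mean(x)
  )
}

#' Histogram of species synchrony indices
#'
#' @param index tibble from [synchrony_index()].
#' @param binwidth histogram bin width.
#' @return a ggplot object.
#' @export
plot_synchrony_distribution <- function(index, binwidth = 0.05) {
  ggplot2::ggplot(index, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "synchrony index (mean pairwise r)",
                  y = "number of species") +
    ggplot2::theme_minimal()
}
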