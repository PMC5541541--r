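#' Map a calendar month to its water-year season
#'
#' The water year starts in autumn of the previous calendar year, matching
#' the regional precipitation cycle: autumn is Sep-Nov of the previous
#' calendar year, winter is Dec of the previous year plus Jan-Feb of the
#' current year, spring Mar-May and summer Jun-Aug.
#'
#' @param year calendar year (vectorized).
#' @param month calendar month 1-12 (vectorized, recycled with `year`).
#' @return tibble with `year`, `month`, `water_year`, `season`.
#' @export
#' @examples
#' water_year_season(1999, 9)   # autumn of water year 2000
#' water_year_season(1999, 12)  # winter of water year 2000
water_year_season <- function(year, month) {
  n <- max(length(year), length(month))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  if (any(!month %in% 1:12)) {
    stop_validation("month must be in 1..12")
  }
  season <- dplyr::case_when(
    month %in% 9:11 ~ "autumn",
    month == 12 | month %in% 1:2 ~ "winter",
    month %in% 3:5 ~ "spring",
    TRUE ~ "summer"
  )
  water_year <- ifelse(month >= 9, year + 1L, year)
  tibble(year = year, month = month,
         water_year = as.integer(water_year), season = season)
}

season_variables <- function() {
  c("winter_temp", "spring_temp", "summer_temp", "autumn_temp",
    "winter_precip", "spring_precip", "summer_precip", "autumn_precip")
}

#' Aggregate monthly weather to z-scored water-year seasonal values
#'
#' Seasonal temperature is the mean of the three monthly means; seasonal
#' precipitation is the sum of the three monthly totals. Values are then
#' z-scored within site x variable across water years, so that regression
#' coefficients on these predictors are comparable across sites. Seasons
#' with fewer than three months of data (typically the boundary water years)
#' are flagged incomplete and excluded from z-scoring.
#'
#' @param weather monthly weather tibble as from [read_weather()].
#' @return tibble with `site_id`, `water_year`, `variable` (one of
#'   `r paste(season_variables(), collapse = ", ")`), `raw`, `z`,
#'   and `complete` (logical).
#' @export
aggregate_seasonal <- function(weather) {
  mapped <- weather |>
    mutate(water_year_season(.data$year, .data$month)[, c("water_year",
                                                          "season")])
  long <- mapped |>
    pivot_longer(c("tmean", "precip"), names_to = "kind",
                 values_to = "value") |>
    group_by(.data$site_id, .data$water_year, .data$season, .data$kind) |>
    summarise(
      raw = if (dplyr::first(.data$kind) == "tmean") mean(.data$value)
            else sum(.data$value),
      n_months = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      variable = paste0(.data$season,
                        ifelse(.data$kind == "tmean", "_temp", "_precip")),
      complete = .data$n_months == 3L,
      raw = ifelse(.data$complete, .data$raw, NA_real_)
    )
  long |>
    group_by(.data$site_id, .data$variable) |>
    mutate(z = {
      ok <- .data$complete & is.finite(.data$raw)
      z <- rep(NA_real_, dplyr::n())
      if (sum(ok) >= 2 && sd(.data$raw[ok]) > 0) {
        z[ok] <- zscore(.data$raw[ok])
      } else if (sum(ok) >= 1) {
        z[ok] <- 0
      }
      z
    }) |>
    ungroup() |>
    select("site_id", "water_year", "variable", "raw", "z", "complete") |>
    arrange(.data$site_id, .data$water_year, .data$variable)
}

#' Winter-mean ENSO index from a monthly SSTA series
#'
#' For each water year, averages the sea-surface-temperature anomaly of
#' December (previous calendar year), January and February -- the peak of
#' ENSO. Water years missing any of the three months get no value. A
#' z-scored variant (across water years) is stored alongside the raw mean
#' so the index can enter models on the same scale as the weather
#' predictors.
#'
#' @param ssta monthly SSTA tibble as from [read_ssta()].
#' @return tibble with `water_year`, `ssta_winter_mean`, `ssta_z`.
#' @export
enso_winter_mean <- function(ssta) {
  djf <- ssta |>
    filter(.data$month %in% c(12L, 1L, 2L)) |>
    mutate(water_year = ifelse(.data$month == 12L,
                               .data$year + 1L, .data$year)) |>
    group_by(.data$water_year) |>
    summarise(ssta_winter_mean = mean(.data$ssta), n_months = dplyr::n(),
              .groups = "drop") |>
    filter(.data$n_months == 3L) |>
    select(-"n_months")
  djf$ssta_z <- if (nrow(djf) >= 2 && sd(djf$ssta_winter_mean) > 0) {
    zscore(djf$ssta_winter_mean)
  } else {
    rep(0, nrow(djf))
  }
  djf
}

#' Cross-site redundancy diagnostic for seasonal weather
#'
#' Reports how strongly the seasonal weather signal is shared across sites:
#' (a) for each seasonal variable, the mean pairwise cross-site Pearson
#' correlation of yearly values, and (b) a principal-component decomposition
#' of the (water-year) x (site x variable) matrix. Two summary readings are
#' reported -- the mean cross-site correlation averaged over variables, and
#' the variance share of the first principal component -- because "how
#' redundant is weather across sites" admits both. Diagnostic only; nothing
#' downstream consumes it.
#'
#' @param seasonal tibble from [aggregate_seasonal()].
#' @return list with `per_variable` (tibble: variable, mean_r, n_pairs),
#'   `mean_cross_site_correlation`, `pc1_variance_share`, and `pca`
#'   (the `prcomp` object).
#' @export
weather_redundancy_diagnostic <- function(seasonal) {
  seasonal <- filter(seasonal, .data$complete, is.finite(.data$raw))
  if (dplyr::n_distinct(seasonal$site_id) < 2) {
    stop_validation("redundancy diagnostic needs at least 2 sites")
  }
  if (dplyr::n_distinct(seasonal$water_year) < 2) {
    stop_validation("redundancy diagnostic needs at least 2 years")
  }
  per_variable <- seasonal |>
    group_by(.data$variable) |>
    group_modify(function(d, key) {
      wide <- pivot_wider(d[, c("water_year", "site_id", "raw")],
                          names_from = "site_id", values_from = "raw")
      m <- as.matrix(wide[, -1, drop = FALSE])
      cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
      rs <- cc[upper.tri(cc)]
      tibble(mean_r = mean(rs, na.rm = TRUE),
             n_pairs = sum(is.finite(rs)))
    }) |>
    ungroup()
  wide_all <- seasonal |>
    mutate(col = paste(.data$site_id, .data$variable, sep = ".")) |>
    select("water_year", "col", "raw") |>
    pivot_wider(names_from = "col", values_from = "raw")
  m <- as.matrix(wide_all[, -1, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  pca <- stats::prcomp(m, scale. = TRUE)
  ev <- pca$sdev^2
  list(
    per_variable = per_variable,
    mean_cross_site_correlation = mean(per_variable$mean_r, na.rm = TRUE),
    pc1_variance_share = ev[1] / sum(ev),
    pca = pca
  )
}
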