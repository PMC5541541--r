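#' Default column-name schema for input tables
#'
#' Monitoring datasets name their columns inconsistently, so every reader
#' accepts a schema map from the canonical names used throughout popsync to
#' the names found in the file. The default maps every canonical name to
#' itself.
#'
#' @param ... named overrides, e.g. `species_id = "taxon"`.
#' @return named character vector (canonical name -> file column name).
#' @export
#' @examples
#' default_schema(species_id = "taxon", detected = "seen")
default_schema <- function(...) {
  schema <- c(
    site_id = "site_id", year = "year", visit_index = "visit_index",
    date = "date", species_id = "species_id", detected = "detected",
    month = "month", tmean = "tmean", precip = "precip", ssta = "ssta",
    wingspan = "wingspan", geographic_range = "geographic_range",
    diet_breadth = "diet_breadth", elevational_range = "elevational_range",
    migratory = "migratory"
  )
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(schema))
    if (length(unknown)) {
      stop_schema(glue::glue(
        "unknown schema field(s): {paste(unknown, collapse = ', ')}"
      ))
    }
    schema[names(dots)] <- dots
  }
  schema
}

read_csv_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("file not found: {path}"), class = "popsync_error_io")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

require_columns <- function(df, schema, canonical, path) {
  wanted <- unname(schema[canonical])
  missing <- setdiff(wanted, names(df))
  if (length(missing)) {
    stop_schema(glue::glue(
      "{path}: missing required column(s): {paste(missing, collapse = ', ')}"
    ))
  }
  df <- df[, wanted, drop = FALSE]
  names(df) <- canonical
  as_tibble(df)
}

report_bad_rows <- function(bad, what) {
  if (!any(bad)) {
    return(invisible(NULL))
  }
  rows <- which(bad)
  shown <- paste(head(rows, 10), collapse = ", ")
  stop_validation(glue::glue(
    "{sum(bad)} row(s) failed validation ({what}); rows: {shown}",
    if (length(rows) > 10) " ..." else ""
  ), bad_rows = rows)
}

#' Read and validate a visit-level observation table
#'
#' One row per site visit per species with a 0/1 detection flag. Dates may be
#' supplied either as `(year, visit_index)` or as a full `date` column; full
#' dates are collapsed to `(year, visit_index)` by within-year rank. Missing
#' visits are represented by absence of rows, never by zero-filled rows.
#'
#' @param path CSV file path.
#' @param schema column-name map from [default_schema()].
#' @return tibble with columns `site_id`, `year`, `visit_index`,
#'   `species_id`, `detected` (integer 0/1); key
#'   `(site_id, year, visit_index, species_id)` is unique.
#' @export
read_observations <- function(path, schema = default_schema()) {
  df <- read_csv_quiet(path)
  has_date <- unname(schema["date"]) %in% names(df) &&
    !(unname(schema["visit_index"]) %in% names(df))
  if (has_date) {
    df <- require_columns(df, schema,
      c("site_id", "date", "species_id", "detected"), path)
    dt <- as.Date(df$date)
    report_bad_rows(is.na(dt), "unparseable date")
    df$year <- as.integer(format(dt, "%Y"))
    # within-year rank of distinct dates per site
    df <- df |>
      group_by(.data$site_id, .data$year) |>
      mutate(visit_index = match(as.Date(.data$date),
                                 sort(unique(as.Date(.data$date))))) |>
      ungroup() |>
      select(-"date")
  } else {
    df <- require_columns(df, schema,
      c("site_id", "year", "visit_index", "species_id", "detected"), path)
  }
  report_bad_rows(!is.finite(df$year) | df$year != floor(df$year),
    "year must be an integer")
  report_bad_rows(!is.finite(df$visit_index) | df$visit_index < 1,
    "visit_index must be a positive integer")
  det <- df$detected
  if (is.logical(det)) det <- as.integer(det)
  report_bad_rows(!det %in% c(0L, 1L), "detected must be 0/1")
  out <- tibble(
    site_id = as.character(df$site_id),
    year = as.integer(df$year),
    visit_index = as.integer(df$visit_index),
    species_id = as.character(df$species_id),
    detected = as.integer(det)
  )
  dup <- duplicated(out[, c("site_id", "year", "visit_index", "species_id")])
  if (any(dup)) {
    keys <- out[dup, c("site_id", "year", "visit_index", "species_id")]
    shown <- do.call(paste, c(head(keys, 5), sep = "/"))
    stop_integrity(glue::glue(
      "duplicate (site, year, visit, species) key(s): ",
      "{paste(shown, collapse = '; ')}"
    ), duplicate_keys = keys)
  }
  out
}

#' Read and validate a monthly site weather table
#'
#' @param path CSV file path with one row per site x year x month.
#' @param schema column-name map from [default_schema()].
#' @return tibble with `site_id`, `year`, `month`, `tmean` (degrees C),
#'   `precip` (mm, non-negative).
#' @export
read_weather <- function(path, schema = default_schema()) {
  df <- read_csv_quiet(path)
  df <- require_columns(df, schema,
    c("site_id", "year", "month", "tmean", "precip"), path)
  report_bad_rows(!df$month %in% 1:12, "month must be in 1..12")
  report_bad_rows(!is.finite(df$precip) | df$precip < 0,
    "precip must be finite and >= 0")
  report_bad_rows(!is.finite(df$tmean), "tmean must be finite")
  out <- tibble(
    site_id = as.character(df$site_id), year = as.integer(df$year),
    month = as.integer(df$month), tmean = as.numeric(df$tmean),
    precip = as.numeric(df$precip)
  )
  dup <- duplicated(out[, c("site_id", "year", "month")])
  if (any(dup)) {
    stop_integrity("duplicate (site, year, month) rows in weather table")
  }
  out
}

#' Read and validate a monthly sea-surface-temperature-anomaly series
#'
#' @param path CSV file path with one row per year x month.
#' @param schema column-name map from [default_schema()].
#' @return tibble with `year`, `month`, `ssta` (degrees C anomaly).
#' @export
read_ssta <- function(path, schema = default_schema()) {
  df <- read_csv_quiet(path)
  df <- require_columns(df, schema, c("year", "month", "ssta"), path)
  report_bad_rows(!df$month %in% 1:12, "month must be in 1..12")
  report_bad_rows(!is.finite(df$ssta), "ssta must be finite")
  out <- tibble(
    year = as.integer(df$year), month = as.integer(df$month),
    ssta = as.numeric(df$ssta)
  )
  if (any(duplicated(out[, c("year", "month")]))) {
    stop_integrity("duplicate (year, month) rows in SSTA table")
  }
  out
}

#' Read and validate a species trait table
#'
#' Traits proxy dispersal propensity: wingspan (mm, species mean of the
#' reported range), geographical range (km^2), diet breadth (number of larval
#' host-plant genera), elevational range (m), plus a migratory flag.
#'
#' @param path CSV file path with one row per species.
#' @param schema column-name map from [default_schema()].
#' @return tibble with `species_id`, the four positive numeric traits and
#'   logical `migratory`.
#' @export
read_traits <- function(path, schema = default_schema()) {
  df <- read_csv_quiet(path)
  df <- require_columns(df, schema,
    c("species_id", "wingspan", "geographic_range", "diet_breadth",
      "elevational_range", "migratory"), path)
  for (v in c("wingspan", "geographic_range", "diet_breadth",
              "elevational_range")) {
    report_bad_rows(!is.finite(df[[v]]) | df[[v]] <= 0,
      glue::glue("{v} must be finite and > 0"))
  }
  mig <- df$migratory
  if (!is.logical(mig)) mig <- as.logical(mig)
  report_bad_rows(is.na(mig), "migratory flag must be present (TRUE/FALSE)")
  out <- tibble(
    species_id = as.character(df$species_id),
    wingspan = as.numeric(df$wingspan),
    geographic_range = as.numeric(df$geographic_range),
    diet_breadth = as.numeric(df$diet_breadth),
    elevational_range = as.numeric(df$elevational_range),
    migratory = mig
  )
  if (any(duplicated(out$species_id))) {
    stop_integrity("duplicate species_id rows in trait table")
  }
  out
}

#' Write a result table to CSV or JSON
#'
#' Values are written at full precision so that reading the file back
#' reproduces them exactly as stored.
#'
#' @param table nonempty data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `invisible(path)`.
#' @export
write_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("refusing to write an empty table", class = "popsync_error_io")
  }
  if (format == "csv") {
    # serialize doubles at 17 significant digits so the round-trip is
    # bit-exact (shortest-representation writers can drop the last ulp)
    out <- table
    for (v in names(out)) {
      if (is.double(out[[v]])) {
        out[[v]] <- ifelse(is.na(out[[v]]), NA_character_,
                           sprintf("%.17g", out[[v]]))
      }
    }
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
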