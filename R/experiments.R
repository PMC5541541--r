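#' Species-removal experiments for a SEM
#'
#' Two sensitivity experiments on a fitted model's explained variance:
#' `mode = "migrants"` refits once after removing all species flagged
#' migratory (the extreme dispersers); `mode = "random"` refits `reps`
#' times, each dropping `n_remove` species sampled uniformly at random,
#' and summarizes the per-replicate R-squared of the outcome with its mean
#' and a distribution-free 95% percentile interval. Replicates whose fit
#' fails to converge are dropped and counted. Reproducible under `seed`.
#'
#' @param spec a [sem_spec()].
#' @param data species-level data frame; must contain a logical
#'   `migratory` column for `mode = "migrants"`.
#' @param mode `"random"` or `"migrants"`.
#' @param n_remove species removed per random replicate.
#' @param reps number of random replicates, or `"exhaustive"` to refit on
#'   every possible subset (only sensible for tiny problems).
#' @param seed integer seed.
#' @param outcome endogenous variable whose R-squared is tracked.
#' @return a `sem_experiment`: list with `mode`, `outcome`, `replicates`
#'   (tibble of per-replicate R-squared), `mean`, `ci` (2.5% and 97.5%
#'   percentiles), `full_r2`, `n_full`, `n_refit`, `n_failed`.
#' @export
exclusion_experiment <- function(spec, data, mode = c("random", "migrants"),
                                 n_remove = 9, reps = 1000, seed = 1L,
                                 outcome = "synchrony") {
  mode <- match.arg(mode)
  n <- nrow(data)
  full_fit <- sem_fit(spec, data)
  full_r2 <- sem_r2(full_fit, outcome)
  if (mode == "migrants") {
    if (!"migratory" %in% names(data)) {
      stop_validation("mode = 'migrants' needs a logical migratory column")
    }
    keep <- !data$migratory
    fit <- sem_fit(spec, data[keep, , drop = FALSE])
    reps_tbl <- tibble(rep = 1L, r2 = sem_r2(fit, outcome),
                       n = sum(keep))
    out <- list(
      mode = mode, outcome = outcome, replicates = reps_tbl,
      mean = reps_tbl$r2, ci = rep(reps_tbl$r2, 2),
      full_r2 = full_r2, n_full = n, n_refit = sum(keep), n_failed = 0L,
      fit = fit
    )
    return(structure(out, class = "sem_experiment"))
  }
  if (n_remove >= n) {
    stop_validation("n_remove must be smaller than the number of species")
  }
  keeps <- if (identical(reps, "exhaustive")) {
    drop_sets <- utils::combn(n, max(n_remove, 1), simplify = FALSE)
    if (n_remove == 0) drop_sets <- list(integer(0))
    map(drop_sets, function(d) setdiff(seq_len(n), d))
  } else {
    NULL
  }
  refit_r2 <- function(keep) {
    tryCatch(
      sem_r2(sem_fit(spec, data[keep, , drop = FALSE],
                     max_restarts = 1), outcome),
      error = function(e) NA_real_
    )
  }
  r2s <- with_seed(derive_seed(seed, "random-removal"), {
    if (!is.null(keeps)) {
      imap(keeps, function(keep, r) {
        tibble(rep = r, r2 = refit_r2(keep), n = length(keep))
      }) |>
        list_rbind()
    } else {
      map(seq_len(reps), function(r) {
        keep <- if (n_remove == 0) seq_len(n) else {
          sort(sample.int(n, n - n_remove))
        }
        tibble(rep = r, r2 = refit_r2(keep), n = length(keep))
      }) |>
        list_rbind()
    }
  })
  ok <- is.finite(r2s$r2)
  vals <- r2s$r2[ok]
  structure(
    list(
      mode = mode, outcome = outcome, replicates = r2s,
      mean = mean(vals),
      ci = quantile(vals, c(0.025, 0.975), names = FALSE),
      full_r2 = full_r2, n_full = n, n_refit = n - n_remove,
      n_failed = sum(!ok)
    ),
    class = "sem_experiment"
  )
}

#' @export
print.sem_experiment <- function(x, digits = 3, ...) {
  cat("Removal experiment (", x$mode, "): mean R^2(", x$outcome, ") = ",
      round(x$mean, digits), " [", round(x$ci[1], digits), ", ",
      round(x$ci[2], digits), "], full-data R^2 = ",
      round(x$full_r2, digits), ", n refit = ", x$n_refit,
      if (x$n_failed) paste0(", ", x$n_failed, " failed replicate(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Compare removal experiments across models
#'
#' Bar-and-interval plot of mean explained variance per experiment, in the
#' style used to contrast dispersal/climate/combined models with and
#' without migrants.
#'
#' @param experiments named list of `sem_experiment` objects.
#' @return a ggplot object.
#' @export
plot_experiments <- function(experiments) {
  d <- imap(experiments, function(e, nm) {
    tibble(model = nm, mean = e$mean, lo = e$ci[1], hi = e$ci[2])
  }) |>
    list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "variance explained (R^2)") +
    ggplot2::theme_minimal()
}
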