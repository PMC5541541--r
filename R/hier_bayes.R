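#' Build the per-species design for the climate-response model
#'
#' Joins a species' FDP records to the z-scored seasonal predictors and the
#' ENSO winter index on site and water year (the observation calendar year
#' is the water year: the flight season falls entirely inside it). The year
#' covariate is centered on the window midpoint and scaled to unit standard
#' deviation, like the weather predictors. Site-years with FDP but missing
#' climate are dropped and logged.
#'
#' @param species_id species to model.
#' @param fdp tibble from [compute_fdp()] (after inclusion rules).
#' @param seasonal tibble from [aggregate_seasonal()].
#' @param enso tibble from [enso_winter_mean()].
#' @return tibble with `site_id`, `water_year`, `positives`, `visits` and
#'   the seven predictors (`winter_temp`, `spring_temp`, `winter_precip`,
#'   `spring_precip`, `summer_precip`, `ssta`, `year`); attribute
#'   `"dropped"` lists excluded site-years.
#' @export
build_design <- function(species_id, fdp, seasonal, enso) {
  sp <- filter(fdp, .data$species_id == .env$species_id)
  if (nrow(sp) == 0) {
    stop_validation(glue::glue("no FDP records for species {species_id}"))
  }
  climate <- seasonal |>
    filter(.data$variable %in% model_terms()) |>
    select("site_id", "water_year", "variable", "z") |>
    pivot_wider(names_from = "variable", values_from = "z")
  out <- sp |>
    select("site_id", water_year = "year", "positives", "visits") |>
    left_join(climate, by = c("site_id", "water_year")) |>
    left_join(select(enso, "water_year", ssta = "ssta_z"),
              by = "water_year")
  weather_terms <- setdiff(model_terms(), "year")
  ok <- stats::complete.cases(out[, weather_terms])
  dropped <- out[!ok, c("site_id", "water_year")]
  out <- out[ok, , drop = FALSE]
  if (nrow(out) < 2) {
    stop_validation("fewer than 2 usable site-years after climate join")
  }
  out$year <- zscore(out$water_year, allow_constant = TRUE)
  structure(out, dropped = dropped, species_id = species_id)
}

hb_default_priors <- function() {
  # sampler-convention hyperpriors: Normal(mean, precision),
  # Gamma(shape, rate); N(0, 1e-5) therefore means variance 1e5
  list(mean_prec = 1e-5, tau_shape = 0.1, tau_rate = 1e-3)
}

hb_matrices <- function(design) {
  terms <- model_terms()
  x <- cbind(intercept = 1, as.matrix(design[, terms]))
  sites <- sort(unique(design$site_id))
  list(
    x = x,
    y = as.numeric(design$positives),
    v = as.numeric(design$visits),
    s = match(design$site_id, sites),
    sites = sites,
    terms = terms
  )
}

#' Joint log posterior density of the hierarchical model
#'
#' Binomial likelihood through the inverse-logit link, Normal site-level
#' pooling distributions parameterized by (mean, precision), and the
#' uninformative hyperpriors Normal(0, 1e-5 precision) on the transect-wide
#' means and Gamma(0.1 shape, 1e-3 rate) on the precisions; returned up to
#' an additive constant. Used directly by tests as an oracle and by the
#' sampler through its incremental form.
#'
#' @param state list with `mu` (length J), `beta` (J x 7 matrix), `mu_mu`,
#'   `mu_beta` (length 7), `tau_mu`, `tau_beta` (length 7).
#' @param design tibble from [build_design()].
#' @param priors list as [popsync:::hb_default_priors].
#' @return scalar log density (`-Inf` for non-positive precisions).
#' @export
log_posterior <- function(state, design, priors = hb_default_priors()) {
  if (any(c(state$tau_mu, state$tau_beta) <= 0)) {
    return(-Inf)
  }
  m <- hb_matrices(design)
  theta <- cbind(state$mu, state$beta)
  alpha <- rowSums(m$x * theta[m$s, , drop = FALSE])
  ll <- sum(m$y * alpha - m$v * log1pexp(alpha))
  hyper_mu <- c(state$mu_mu, state$mu_beta)
  tau <- c(state$tau_mu, state$tau_beta)
  lp_site <- sum(vapply(seq_len(ncol(theta)), function(k) {
    sum(0.5 * log(tau[k]) - 0.5 * tau[k] * (theta[, k] - hyper_mu[k])^2)
  }, numeric(1)))
  lp_hyper <- sum(-0.5 * priors$mean_prec * hyper_mu^2) +
    sum((priors$tau_shape - 1) * log(tau) - priors$tau_rate * tau)
  ll + lp_site + lp_hyper
}

# closed-form conjugate conditionals for the transect-wide parameters,
# given the site-level values: normal-normal for the mean (precision =
# prior precision + J * tau), gamma for the precision
gibbs_mean_update <- function(theta_col, tau, priors) {
  j <- length(theta_col)
  prec <- priors$mean_prec + j * tau
  rnorm(1, tau * sum(theta_col) / prec, sqrt(1 / prec))
}

gibbs_prec_update <- function(theta_col, hyper_mu, priors) {
  j <- length(theta_col)
  rgamma(1, shape = priors$tau_shape + j / 2,
         rate = priors$tau_rate + 0.5 * sum((theta_col - hyper_mu)^2))
}

run_one_chain <- function(m, n_iter, burn_in, priors) {
  J <- length(m$sites)
  K <- 8L # intercept + 7 slopes
  theta <- matrix(0, J, K)
  hyper_mu <- numeric(K)
  tau <- rep(1, K)
  step <- matrix(0.4, J, K)
  alpha <- rep(0, length(m$y))
  ll_site <- rowsum(m$y * alpha - m$v * log1pexp(alpha), m$s)[, 1]

  n_total <- burn_in + n_iter
  n_par <- J * K + 2L * K
  draws <- matrix(NA_real_, n_iter, n_par)
  acc_count <- matrix(0, J, K)

  for (t in seq_len(n_total)) {
    adapting <- t <= burn_in
    for (k in seq_len(K)) {
      cur <- theta[, k]
      prop <- cur + step[, k] * rnorm(J)
      d_alpha <- m$x[, k] * (prop - cur)[m$s]
      alpha_prop <- alpha + d_alpha
      d_ll <- rowsum(m$y * d_alpha -
                       m$v * (log1pexp(alpha_prop) - log1pexp(alpha)),
                     m$s)[, 1]
      d_prior <- -0.5 * tau[k] *
        ((prop - hyper_mu[k])^2 - (cur - hyper_mu[k])^2)
      accept <- log(runif(J)) < d_ll + d_prior
      if (any(accept)) {
        theta[accept, k] <- prop[accept]
        rows <- accept[m$s]
        alpha[rows] <- alpha_prop[rows]
        ll_site[accept] <- ll_site[accept] + d_ll[accept]
      }
      if (adapting) {
        step[, k] <- step[, k] * exp(t^(-0.6) * (accept - 0.37))
      } else {
        acc_count[, k] <- acc_count[, k] + accept
      }
    }
    # conjugate Gibbs updates given site-level values
    for (k in seq_len(K)) {
      hyper_mu[k] <- gibbs_mean_update(theta[, k], tau[k], priors)
      tau[k] <- gibbs_prec_update(theta[, k], hyper_mu[k], priors)
    }
    if (!adapting) {
      draws[t - burn_in, ] <- c(theta, hyper_mu, tau)
    }
  }
  list(draws = draws, step = step, acc_rate = acc_count / n_iter)
}

hb_param_names <- function(sites, terms) {
  coef_names <- c("mu", paste0("beta_", terms))
  c(
    as.vector(outer(coef_names, sites,
                    function(p, s) paste0(p, "[", s, "]"))),
    paste0("mu_", coef_names),
    paste0("tau_", coef_names)
  )
}

#' Fit the hierarchical climate-response model by MCMC
#'
#' Gibbs-within-Metropolis sampler: transect-wide means and precisions are
#' updated by their normal-normal and gamma conjugate conditionals; each
#' site-level intercept and slope by adaptive random-walk Metropolis whose
#' step sizes adapt toward ~37% acceptance during burn-in only (adaptation
#' frozen afterwards, preserving detailed balance). Identical seeds give
#' identical draws.
#'
#' @param design tibble from [build_design()].
#' @param n_iter retained iterations per chain after burn-in. The default
#'   is the desk-scale protocol; the full-length analysis uses
#'   `n_iter = 30000, burn_in = 1000`.
#' @param burn_in discarded adaptation iterations.
#' @param chains number of chains (2 or more enables R-hat).
#' @param seed integer seed.
#' @param priors hyperprior settings (see [log_posterior()]).
#' @return an object of class `hb_draws`: list with `draws` (array
#'   iterations x parameters x chains), `sites`, `terms`, `species_id`,
#'   `acc_rate`.
#' @export
run_mcmc <- function(design, n_iter = 5000, burn_in = 1000, chains = 2,
                     seed = 1L, priors = hb_default_priors()) {
  if (nrow(design) == 0) {
    stop_validation("empty design")
  }
  m <- hb_matrices(design)
  if (length(m$sites) < 2) {
    stop_validation("hierarchical model needs at least 2 sites")
  }
  if (chains < 2) {
    warn("fewer than 2 chains: split R-hat will be unavailable")
  }
  res <- map(seq_len(chains), function(ch) {
    with_seed(derive_seed(seed, "mcmc", ch), {
      run_one_chain(m, n_iter, burn_in, priors)
    })
  })
  nm <- hb_param_names(m$sites, m$terms)
  draws <- array(
    unlist(map(res, "draws")),
    dim = c(n_iter, length(nm), chains),
    dimnames = list(NULL, nm, paste0("chain", seq_len(chains)))
  )
  structure(
    list(draws = draws, sites = m$sites, terms = m$terms,
         species_id = attr(design, "species_id", exact = TRUE),
         acc_rate = map(res, "acc_rate")),
    class = "hb_draws"
  )
}

# split-chain R-hat and rank-free ESS for one parameter's draw matrix
# (iterations x chains)
split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(h), j], mat[(n - h + 1):n, j])
  }))
}

rhat_one <- function(mat) {
  sm <- split_chains(mat)
  n <- nrow(sm)
  mns <- colMeans(sm)
  vars <- apply(sm, 2, var)
  w <- mean(vars)
  b <- n * var(mns)
  if (w == 0) {
    return(if (b == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_one <- function(mat) {
  n <- nrow(mat)
  m_ch <- ncol(mat)
  vars <- apply(mat, 2, var)
  w <- mean(vars)
  if (w == 0) {
    return(NA_real_)
  }
  b <- if (m_ch > 1) n * var(colMeans(mat)) else 0
  var_plus <- (n - 1) / n * w + b / n
  max_lag <- min(n - 2, 1000)
  # chain-averaged autocovariances
  acov <- rowMeans(sapply(seq_len(m_ch), function(j) {
    a <- acf(mat[, j], lag.max = max_lag, plot = FALSE,
             type = "covariance", demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }))
  rho <- 1 - (w - acov[-1]) / var_plus
  # Geyer initial positive + monotone sequence on paired sums
  n_pairs <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  if (n_pairs >= 1) {
    for (i in seq_len(n_pairs)) {
      pair <- rho[2 * i - 1] + rho[2 * i]
      if (pair < 0) break
      pair <- min(pair, prev)
      prev <- pair
      tau <- tau + 2 * pair
    }
  }
  min(n * m_ch / tau, n * m_ch)
}

#' Convergence diagnostics for MCMC draws
#'
#' Standard split-chain R-hat and autocorrelation-based effective sample
#' size per parameter.
#'
#' @param fit an `hb_draws` object from [run_mcmc()], or a plain
#'   iterations x chains matrix for a single parameter.
#' @return tibble with `param`, `ess`, `rhat` (`rhat` is `NA` with a
#'   warning when only one chain is available).
#' @export
diagnose <- function(fit) {
  if (is.matrix(fit)) {
    draws <- array(fit, dim = c(nrow(fit), 1, ncol(fit)),
                   dimnames = list(NULL, "x", NULL))
  } else {
    draws <- fit$draws
  }
  single <- dim(draws)[3] < 2
  if (single) {
    warn("single chain: split R-hat omitted")
  }
  params <- dimnames(draws)[[2]]
  tibble(
    param = params,
    ess = map_dbl(params, function(p) ess_one(draws[, p, ])),
    rhat = if (single) NA_real_ else {
      map_dbl(params, function(p) rhat_one(draws[, p, ]))
    }
  )
}

#' Posterior summary and species climate response
#'
#' Per-parameter posterior mean, sd, central 95% interval, ESS and split
#' R-hat. The species' climate response is the vector of posterior means
#' of the seven transect-wide slope parameters (`mu_beta_*`), the point
#' estimates used downstream.
#'
#' @param fit an `hb_draws` object from [run_mcmc()].
#' @param diagnostics also compute ESS/R-hat (slower).
#' @return a `hb_summary` tibble; attribute `"response"` holds the named
#'   7-vector of transect-wide slope posterior means.
#' @export
summarize_draws <- function(fit, diagnostics = TRUE) {
  draws <- fit$draws
  flat <- apply(draws, 2, identity) # (iter*chain) x param
  out <- tibble(
    param = dimnames(draws)[[2]],
    mean = unname(colMeans(flat)),
    sd = unname(apply(flat, 2, sd)),
    q2.5 = unname(apply(flat, 2, quantile, 0.025, names = FALSE)),
    q97.5 = unname(apply(flat, 2, quantile, 0.975, names = FALSE))
  )
  if (diagnostics) {
    out <- left_join(out, suppressWarnings(diagnose(fit)), by = "param")
  }
  resp <- out$mean[match(paste0("mu_beta_", fit$terms), out$param)]
  names(resp) <- fit$terms
  structure(out, response = resp, species_id = fit$species_id,
            class = c("hb_summary", class(out)))
}

#' @export
#' @rdname summarize_draws
species_response <- function(fit) {
  if (inherits(fit, "hb_draws")) fit <- summarize_draws(fit, FALSE)
  attr(fit, "response", exact = TRUE)
}

#' Fit climate-response models for many species
#'
#' Runs [build_design()] + [run_mcmc()] + [summarize_draws()] per species
#' with per-species seeds derived deterministically from the master seed,
#' so results do not depend on execution order.
#'
#' @param fdp FDP tibble after inclusion rules.
#' @param seasonal,enso climate predictor tibbles.
#' @param species character vector (defaults to all species in `fdp`).
#' @param n_iter,burn_in,chains sampler settings per [run_mcmc()].
#' @param seed master seed.
#' @return tibble with one row per species: `species_id` and `resp_<term>`
#'   posterior-mean responses.
#' @export
fit_species_responses <- function(fdp, seasonal, enso, species = NULL,
                                  n_iter = 1500, burn_in = 500,
                                  chains = 2, seed = 1L) {
  species <- species %||% sort(unique(fdp$species_id))
  map(species, function(sp) {
    design <- build_design(sp, fdp, seasonal, enso)
    fit <- run_mcmc(design, n_iter = n_iter, burn_in = burn_in,
                    chains = chains, seed = derive_seed(seed, "sp", sp))
    resp <- species_response(fit)
    tibble(species_id = sp, !!!setNames(as.list(resp),
                                        paste0("resp_", names(resp))))
  }) |>
    list_rbind()
}

#' Interval plot of transect-wide climate responses
#'
#' @param summary an `hb_summary` from [summarize_draws()].
#' @return a ggplot object showing posterior means and 95% intervals of
#'   the transect-wide coefficients.
#' @export
plot_climate_response <- function(summary) {
  d <- summary |>
    filter(grepl("^mu_beta_", .data$param)) |>
    mutate(term = sub("^mu_beta_", "", .data$param))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q2.5,
                                          xmax = .data$q97.5)) +
    ggplot2::labs(x = "transect-wide coefficient (posterior mean, 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
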