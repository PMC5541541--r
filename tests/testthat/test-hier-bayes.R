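# small design shared by several blocks
small_design <- function(n_sites = 3, n_years = 15, visits = 25,
                         betas = c(spring_temp = -0.5, ssta = 1),
                         seed = 55) {
  cfg <- sim_config(n_sites = n_sites, n_species = 1, n_years = n_years,
                    visits_per_year = visits)
  env <- simulate_environment(cfg, seed = seed)
  truth <- make_truth(cfg, mu = -0.5, betas = betas, site_sd = 0.15,
                      seed = seed + 1)
  obs <- simulate_observations(env, truth, cfg, seed = seed + 2)
  fdp <- compute_fdp(obs)
  seasonal <- aggregate_seasonal(env$weather)
  enso <- enso_winter_mean(env$ssta)
  list(design = build_design("sp001", fdp, seasonal, enso),
       truth = truth, cfg = cfg)
}

test_that("the design matrix has one z-scored row per usable site-year", {
  d <- small_design(n_sites = 3, n_years = 25)
  des <- d$design
  expect_equal(nrow(des), 75)
  for (v in popsync:::model_terms()) {
    expect_lt(abs(mean(des[[v]])), 1 + 1e-10) # finite, no NA
    expect_false(anyNA(des[[v]]))
  }
  # year covariate is centered and unit-scaled
  expect_lt(abs(mean(des$year)), 1e-10)
  expect_lt(abs(sd(des$year) - 1), 1e-10)
  # dropping one site's winter removes exactly that row, with a log
  d2 <- small_design(n_sites = 3, n_years = 25)
  seasonal <- aggregate_seasonal(
    simulate_environment(d2$cfg, seed = 55)$weather)
  drop_year <- sort(unique(seasonal$water_year))[3]
  seasonal_gap <- seasonal[!(seasonal$site_id == "S01" &
                               seasonal$water_year == drop_year &
                               seasonal$variable == "winter_temp"), ]
  env <- simulate_environment(d2$cfg, seed = 55)
  enso <- enso_winter_mean(env$ssta)
  obs <- simulate_observations(env, d2$truth, d2$cfg, seed = 57)
  des_gap <- build_design("sp001", compute_fdp(obs), seasonal_gap, enso)
  expect_equal(nrow(des_gap), 74)
  expect_equal(nrow(attr(des_gap, "dropped")), 1)
})

test_that("log_posterior matches an independently coded density oracle", {
  d <- small_design(n_sites = 2, n_years = 8, visits = 10)
  des <- d$design
  terms <- popsync:::model_terms()
  mk_state <- function(shift = 0) {
    list(mu = c(-0.4, -0.6) + shift,
         beta = matrix(seq(-0.3, 0.4, length.out = 14) + shift, 2, 7),
         mu_mu = -0.5 + shift, mu_beta = rep(0.1, 7) - shift,
         tau_mu = 2, tau_beta = rep(1.5, 7))
  }
  oracle <- function(state) {
    x <- cbind(1, as.matrix(des[, terms]))
    sites <- sort(unique(des$site_id))
    th <- cbind(state$mu, state$beta)
    alpha <- rowSums(x * th[match(des$site_id, sites), ])
    ll <- sum(dbinom(des$positives, des$visits, plogis(alpha), log = TRUE))
    hm <- c(state$mu_mu, state$mu_beta)
    tau <- c(state$tau_mu, state$tau_beta)
    lp <- 0
    for (k in 1:8) {
      lp <- lp + sum(dnorm(th[, k], hm[k], 1 / sqrt(tau[k]), log = TRUE))
    }
    lp <- lp + sum(dnorm(hm, 0, sqrt(1e5), log = TRUE))
    lp <- lp + sum(dgamma(tau, shape = 0.1, rate = 1e-3, log = TRUE))
    ll + lp
  }
  s1 <- mk_state(0)
  s2 <- mk_state(0.3)
  # densities are defined up to one additive constant: differences agree
  expect_equal(
    log_posterior(s1, des) - log_posterior(s2, des),
    oracle(s1) - oracle(s2),
    tolerance = 1e-10
  )
  # all-zero coefficients: the likelihood term is sum(v) * log(0.5);
  # isolate it by differencing away the (state-independent) prior terms
  zero <- list(mu = c(0, 0), beta = matrix(0, 2, 7), mu_mu = 0,
               mu_beta = rep(0, 7), tau_mu = 1, tau_beta = rep(1, 7))
  oracle_zero_lik <- sum(dbinom(des$positives, des$visits, 0.5,
                                log = TRUE))
  expect_equal(
    oracle_zero_lik -
      sum(lchoose(des$visits, des$positives)), # strip the constant
    sum(des$visits) * log(0.5)
  )
  # a diverging linear predictor with y < v drives the density down
  huge <- zero
  huge$mu <- c(50, 50)
  expect_lt(log_posterior(huge, des), log_posterior(zero, des) - 100)
  # non-positive precision is rejected outright
  bad <- zero
  bad$tau_mu <- -1
  expect_identical(log_posterior(bad, des), -Inf)
})

test_that("conjugate Gibbs draws match the closed-form conditionals", {
  priors <- popsync:::hb_default_priors()
  theta_col <- c(-0.2, 0.1, 0.4, -0.5, 0.3)
  tau <- 2.5
  withr::with_seed(99, {
    mu_draws <- replicate(5000,
      popsync:::gibbs_mean_update(theta_col, tau, priors))
  })
  prec <- priors$mean_prec + length(theta_col) * tau
  ks_mu <- stats::ks.test(mu_draws, "pnorm",
                          tau * sum(theta_col) / prec, sqrt(1 / prec))
  expect_gt(ks_mu$p.value, 0.01)

  hyper_mu <- 0.05
  withr::with_seed(100, {
    tau_draws <- replicate(5000,
      popsync:::gibbs_prec_update(theta_col, hyper_mu, priors))
  })
  ks_tau <- stats::ks.test(
    tau_draws, "pgamma",
    shape = priors$tau_shape + length(theta_col) / 2,
    rate = priors$tau_rate + 0.5 * sum((theta_col - hyper_mu)^2)
  )
  expect_gt(ks_tau$p.value, 0.01)
})

test_that("chains are bitwise-reproducible under a seed", {
  d <- small_design(n_sites = 2, n_years = 10, visits = 10)
  f1 <- run_mcmc(d$design, n_iter = 200, burn_in = 100, chains = 2,
                 seed = 3)
  f2 <- run_mcmc(d$design, n_iter = 200, burn_in = 100, chains = 2,
                 seed = 3)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(d$design, n_iter = 200, burn_in = 100, chains = 2,
                 seed = 4)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries equal a brute-force recomputation", {
  d <- small_design(n_sites = 2, n_years = 10, visits = 10)
  fit <- run_mcmc(d$design, n_iter = 300, burn_in = 100, chains = 2,
                  seed = 8)
  s <- summarize_draws(fit, diagnostics = FALSE)
  flat <- rbind(fit$draws[, , 1], fit$draws[, , 2])
  i <- match("mu_beta_ssta", s$param)
  expect_equal(s$mean[i], mean(flat[, "mu_beta_ssta"]), tolerance = 1e-12)
  expect_equal(s$sd[i], sd(flat[, "mu_beta_ssta"]), tolerance = 1e-12)
  expect_equal(s$q2.5[i],
               unname(quantile(flat[, "mu_beta_ssta"], 0.025)),
               tolerance = 1e-12)
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  resp <- species_response(fit)
  expect_equal(unname(resp["ssta"]), mean(flat[, "mu_beta_ssta"]),
               tolerance = 1e-12)
  expect_named(resp, popsync:::model_terms())
})

test_that("diagnostics behave on iid, constant and AR(1) chains", {
  withr::with_seed(21, {
    iid <- matrix(rnorm(10000), 5000, 2)
  })
  d_iid <- suppressWarnings(diagnose(iid))
  expect_gt(d_iid$rhat, 0.99)
  expect_lt(d_iid$rhat, 1.01)
  expect_gt(d_iid$ess, 0.8 * 10000)

  const <- cbind(rep(1, 1000), rep(2, 1000))
  d_const <- diagnose(const)
  expect_gt(d_const$rhat, 1.1)

  phi <- 0.9
  withr::with_seed(22, {
    ar <- sapply(1:2, function(ch) {
      x <- numeric(20000)
      x[1] <- rnorm(1)
      for (t in 2:20000) x[t] <- phi * x[t - 1] + rnorm(1) * sqrt(1 - phi^2)
      x
    })
  })
  d_ar <- diagnose(ar)
  ratio <- d_ar$ess / 40000
  theo <- (1 - phi) / (1 + phi)
  expect_gt(ratio, theo / 1.5)
  expect_lt(ratio, theo * 1.5)
})

test_that("the sampler agrees with a JAGS fit of the same model", {
  library(rjags)
  d <- small_design(n_sites = 4, n_years = 20, visits = 30,
                    betas = c(spring_temp = -0.5, ssta = 0.8), seed = 71)
  des <- d$design
  fit <- run_mcmc(des, n_iter = 3000, burn_in = 1000, chains = 2, seed = 9)
  mine <- species_response(fit)

  terms <- popsync:::model_terms()
  x <- as.matrix(des[, terms])
  sites <- match(des$site_id, sort(unique(des$site_id)))
  model_str <- "
    model {
      for (i in 1:N) {
        logit(p[i]) <- mu[s[i]] + inprod(beta[s[i], ], x[i, ])
        y[i] ~ dbin(p[i], v[i])
      }
      for (j in 1:J) {
        mu[j] ~ dnorm(mu_mu, tau_mu)
        for (k in 1:K) { beta[j, k] ~ dnorm(mu_beta[k], tau_beta[k]) }
      }
      mu_mu ~ dnorm(0, 1.0E-5)
      tau_mu ~ dgamma(0.1, 1.0E-3)
      for (k in 1:K) {
        mu_beta[k] ~ dnorm(0, 1.0E-5)
        tau_beta[k] ~ dgamma(0.1, 1.0E-3)
      }
    }"
  jm <- jags.model(
    textConnection(model_str),
    data = list(N = nrow(des), J = max(sites), K = 7, y = des$positives,
                v = des$visits, x = x, s = sites),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7)
  )
  update(jm, 1000, progress.bar = "none")
  post <- coda.samples(jm, c("mu_beta"), n.iter = 3000,
                       progress.bar = "none")
  jags_means <- colMeans(as.matrix(post))
  expect_lt(max(abs(mine - jags_means[paste0("mu_beta[", 1:7, "]")])),
            0.1)
})

test_that("zero between-site heterogeneity is recovered", {
  cfg <- sim_config(n_sites = 4, n_species = 1, n_years = 40,
                    visits_per_year = 40, site_coef_sd = 0)
  env <- simulate_environment(cfg, seed = 61)
  truth <- make_truth(cfg, mu = -0.5, betas = c(ssta = 0.6), site_sd = 0,
                      seed = 62)
  obs <- simulate_observations(env, truth, cfg, seed = 63)
  des <- build_design("sp001", compute_fdp(obs),
                      aggregate_seasonal(env$weather),
                      enso_winter_mean(env$ssta))
  fit <- run_mcmc(des, n_iter = 2000, burn_in = 800, chains = 2, seed = 64)
  flat <- rbind(fit$draws[, , 1], fit$draws[, , 2])
  between_sd <- colMeans(1 / sqrt(
    flat[, paste0("tau_beta_", popsync:::model_terms()), drop = FALSE]))
  expect_true(all(between_sd < 0.1))
})
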