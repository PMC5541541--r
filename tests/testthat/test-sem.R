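# a small identified 2-latent generating model used across blocks
recovery_spec <- function() {
  sem_spec("
    F1 =~ y1 + y2 + y3
    F2 =~ y4 + y5 + y6
    F1 ~~ F2
    out ~ F1 + F2
  ")
}

recovery_theta <- function() {
  # order of spec$params[free]: loadings y2,y3 (F1), y5,y6 (F2),
  # cov(F1,F2), paths out~F1, out~F2, then auto variances:
  # y1..y6, out residual, F1, F2
  c(0.8, 0.7, 0.9, 0.6,
    0.3,
    0.5, -0.4,
    0.36, 0.36, 0.51, 0.19, 0.36, 0.64,
    0.4, 1, 1)
}

test_that("implied covariance follows the RAM closed forms", {
  # no paths, unit variances: identity
  spec0 <- sem_spec("a ~~ 1*a\nb ~~ 1*b\nc ~~ 1*c\na ~~ 0*b")
  expect_equal(implied_sigma(spec0, numeric(0)), diag(3),
               ignore_attr = TRUE)
  # single regression y = b x
  spec1 <- sem_spec("y ~ x")
  # free params: b, y resid psi, var x
  sig <- implied_sigma(spec1, c(0.7, 0.5, 1))
  expect_equal(sig["y", "y"], 0.7^2 + 0.5)
  expect_equal(sig["x", "y"], 0.7)
  expect_equal(sig["x", "x"], 1)
})

test_that("implied covariance matches a large Monte-Carlo simulation", {
  spec <- recovery_spec()
  theta <- recovery_theta()
  sigma <- implied_sigma(spec, theta)
  dat <- sem_simulate(spec, theta, 1e6, seed = 404)
  mc <- cov(as.matrix(dat))
  expect_lt(max(abs(mc - sigma)), 0.01)
})

test_that("model df equals moments minus an independent parameter count", {
  for (m in c("dispersal", "climate", "combined")) {
    spec <- canned_models(m)
    p <- length(spec$observed)
    # independent count: walk the parameter table by type
    pr <- spec$params
    n_load <- sum(pr$matrix == "A" & pr$free &
                    pr$col %in% spec$latents & pr$row %in% spec$observed)
    n_path <- sum(pr$matrix == "A" & pr$free) - n_load
    n_var <- sum(pr$matrix == "S" & pr$free & pr$row == pr$col)
    n_cov <- sum(pr$matrix == "S" & pr$free & pr$row != pr$col)
    expect_equal(sem_df(spec),
                 p * (p + 1) / 2 - (n_load + n_path + n_var + n_cov))
  }
  expect_equal(sem_df(canned_models("dispersal")), 4)
  expect_equal(sem_df(canned_models("climate")), 9)
  expect_equal(sem_df(canned_models("combined")), 18)
})

test_that("a saturated model fits perfectly and F_ML vanishes at S", {
  vars <- c("a", "b", "c")
  sat_lines <- c(
    apply(utils::combn(vars, 2), 2, paste, collapse = " ~~ ")
  )
  spec <- sem_spec(paste(sat_lines, collapse = "\n"))
  withr::with_seed(5, {
    dat <- tibble::as_tibble(as.data.frame(
      matrix(rnorm(600), 200, 3, dimnames = list(NULL, vars))))
  })
  fit <- sem_fit(spec, dat)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_lt(max(abs(fit$sigma - fit$s_samp)), 1e-5)
})

test_that("generating parameters are recovered from simulated data", {
  spec <- recovery_spec()
  theta <- recovery_theta()
  dat <- sem_simulate(spec, theta, 5000, seed = 11)
  fit <- sem_fit(spec, dat)
  td <- tidy(fit)
  # standardized loadings/paths close to the generating standardized values
  gen_sd <- sqrt(diag(popsync:::ram_full_cov(spec, theta)$G))
  names(gen_sd) <- spec$vars
  pr <- spec$params
  gen_std <- vapply(seq_len(nrow(pr)), function(i) {
    vals <- pr$value
    vals[pr$free] <- theta
    if (pr$matrix[i] == "A") {
      vals[i] * gen_sd[pr$col[i]] / gen_sd[pr$row[i]]
    } else {
      vals[i] / (gen_sd[pr$row[i]] * gen_sd[pr$col[i]])
    }
  }, numeric(1))
  free_paths <- pr$free & pr$matrix == "A"
  expect_lt(max(abs(td$std_estimate[free_paths] - gen_std[free_paths])),
            0.05)
  # R2 of the outcome close to the generating value
  gen_r2 <- 1 - 0.4 / popsync:::ram_full_cov(spec, theta)$G["out", "out"]
  expect_lt(abs(sem_r2(fit, "out") - gen_r2), 0.03)
})

test_that("chi-square p-values are roughly uniform under the true model", {
  spec <- recovery_spec()
  theta <- recovery_theta()
  pvals <- vapply(1:100, function(r) {
    dat <- sem_simulate(spec, theta, 400, seed = 6000 + r)
    sem_fit(spec, dat)$pvalue
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("AIC prefers the generating model over an over-restricted one", {
  spec <- recovery_spec()
  theta <- recovery_theta()
  restricted <- sem_spec("
    F1 =~ y1 + y2 + y3
    F2 =~ y4 + y5 + y6
    F1 ~~ F2
    out ~ F1
  ")
  wins <- vapply(1:100, function(r) {
    dat <- sem_simulate(spec, theta, 300, seed = 7000 + r)
    glance(sem_fit(spec, dat))$aic <
      glance(sem_fit(restricted, dat))$aic
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("standardization follows the implied standard deviations", {
  # y = 0.4 x with Var(x) = 4 and unit implied Var(y): std coef 0.8
  spec <- sem_spec("y ~ x\nx ~~ 4*x\ny ~~ 0.36*y")
  fitlike <- list(
    spec = spec, theta = c(0.4),
    full_cov = popsync:::ram_full_cov(spec, c(0.4))$G
  )
  class(fitlike) <- "sem_fit"
  std <- sem_standardize(fitlike)
  lab <- spec$params$label
  expect_equal(std[lab == "y~x"], 0.8, tolerance = 1e-12)
  # brute-force check on a fitted model
  spec2 <- recovery_spec()
  dat <- sem_simulate(spec2, recovery_theta(), 800, seed = 3)
  fit <- sem_fit(spec2, dat)
  sds <- sqrt(diag(fit$full_cov))
  td <- tidy(fit)
  i <- which(td$label == "out~F1")
  expect_equal(td$std_estimate[i],
               unname(td$estimate[i] * sds[which(spec2$vars == "F1")] /
                        sds[which(spec2$vars == "out")]),
               tolerance = 1e-10)
})

test_that("R-squared has its closed forms and guards", {
  # y = 0.8 x + e with everything standardized: R2 = 0.64
  spec <- sem_spec("y ~ x\nx ~~ 1*x\ny ~~ 0.36*y")
  dat <- sem_simulate(spec, c(0.8), 4000, seed = 31)
  fit <- sem_fit(sem_spec("y ~ x"), dat)
  expect_equal(sem_r2(fit, "y"), 0.64, tolerance = 0.05)
  expect_error(sem_r2(fit, "x"), class = "popsync_error_validation")
  # zero path: R2 = 0
  spec0 <- sem_spec("y ~ 0*x")
  dat0 <- tibble::tibble(x = rnorm(300), y = rnorm(300))
  fit0 <- sem_fit(spec0, dat0)
  expect_equal(sem_r2(fit0, "y"), 0, tolerance = 1e-8)
})

test_that("estimates are invariant to variable order and z-scoring", {
  spec <- recovery_spec()
  dat <- sem_simulate(spec, recovery_theta(), 600, seed = 8)
  fit1 <- sem_fit(spec, dat)
  fit2 <- sem_fit(spec, dat[, rev(names(dat))])
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate,
               tolerance = 1e-6)
  dat_z <- dplyr::mutate(dat, dplyr::across(dplyr::everything(),
                                            ~ as.numeric(scale(.x))))
  fit3 <- sem_fit(spec, dat_z)
  expect_equal(tidy(fit1)$std_estimate, tidy(fit3)$std_estimate,
               tolerance = 1e-6)
  expect_equal(fit1$chisq, fit3$chisq, tolerance = 1e-6)
})

test_that("Wald p-values of a true-zero path are approximately uniform", {
  gen <- sem_spec("y ~ x1\ny ~ 0*x2\nx1 ~~ x2")
  fitspec <- sem_spec("y ~ x1 + x2\nx1 ~~ x2")
  pvals <- vapply(1:200, function(r) {
    dat <- sem_simulate(gen, c(0.5, 0.3, 1, 0.75, 1), 150,
                        seed = 9000 + r)
    fit <- sem_fit(fitspec, dat)
    td <- tidy(fit)
    td$p_value[td$label == "y~x2"]
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("non-recursive specifications are rejected", {
  expect_error(sem_spec("a ~ b\nb ~ a"),
               class = "popsync_error_validation")
})

test_that("random-removal machinery matches exhaustive enumeration", {
  spec <- sem_spec("synchrony ~ x\nx ~~ x")
  withr::with_seed(14, {
    dat <- tibble::tibble(x = rnorm(6))
    dat$synchrony <- 0.8 * dat$x + rnorm(6, 0, 0.4)
  })
  ex <- exclusion_experiment(spec, dat, mode = "random", n_remove = 1,
                             reps = "exhaustive", outcome = "synchrony")
  # independent enumeration oracle
  oracle <- mean(vapply(1:6, function(i) {
    sem_r2(sem_fit(spec, dat[-i, ]), "synchrony")
  }, numeric(1)))
  expect_equal(ex$mean, oracle, tolerance = 1e-12)
  expect_equal(nrow(ex$replicates), 6)
})
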