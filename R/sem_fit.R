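# F_ML and its analytic gradient ------------------------------------------

fml_value <- function(spec, theta, s_samp, log_det_s) {
  sigma <- implied_sigma(spec, theta)
  r <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(r)) {
    return(1e10 * (1 + sum(theta^2)))
  }
  log_det <- 2 * sum(log(diag(r)))
  inv <- chol2inv(r)
  log_det + sum(inv * s_samp) - log_det_s - ncol(s_samp)
}

fml_gradient <- function(spec, theta, s_samp) {
  full <- ram_full_cov(spec, theta)
  obs <- spec$observed
  sigma <- full$G[obs, obs, drop = FALSE]
  r <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(r)) {
    return(2e10 * theta)
  }
  inv <- chol2inv(r)
  w <- inv %*% (sigma - s_samp) %*% inv
  m <- matrix(0, length(spec$vars), length(spec$vars),
              dimnames = list(spec$vars, spec$vars))
  m[obs, obs] <- w
  bt_m <- t(full$B) %*% m
  grad_a <- 2 * bt_m %*% full$G       # d F / d A[r, c]
  grad_s_mat <- bt_m %*% full$B       # d F / d S (x2 off-diagonal)
  pr <- spec$params[spec$params$free, , drop = FALSE]
  vapply(seq_len(nrow(pr)), function(i) {
    if (pr$matrix[i] == "A") {
      grad_a[pr$row[i], pr$col[i]]
    } else if (pr$row[i] == pr$col[i]) {
      grad_s_mat[pr$row[i], pr$col[i]]
    } else {
      2 * grad_s_mat[pr$row[i], pr$col[i]]
    }
  }, numeric(1))
}

# heuristic starting values: marker-scaled loadings, data-driven variances
sem_start <- function(spec, s_samp) {
  pr <- spec$params
  vars <- spec$vars
  obs <- spec$observed
  # marker per latent = indicator whose loading is fixed to 1
  markers <- list()
  for (l in spec$latents) {
    fixed_rows <- pr$matrix == "A" & pr$col == l & !pr$free &
      !is.na(pr$value) & pr$value == 1 & pr$row %in% obs
    if (any(fixed_rows)) markers[[l]] <- pr$row[which(fixed_rows)[1]]
  }
  proxy_var <- function(v) {
    if (v %in% obs) {
      s_samp[v, v]
    } else if (!is.null(markers[[v]])) {
      s_samp[markers[[v]], markers[[v]]]
    } else {
      1
    }
  }
  proxy_cov <- function(a, b) {
    av <- if (a %in% obs) a else markers[[a]]
    bv <- if (b %in% obs) b else markers[[b]]
    if (is.null(av) || is.null(bv)) 0 else s_samp[av, bv]
  }
  start <- numeric(sum(pr$free))
  j <- 0
  for (i in seq_len(nrow(pr))) {
    if (!pr$free[i]) next
    j <- j + 1
    if (pr$matrix[i] == "A") {
      denom <- proxy_var(pr$col[i])
      val <- if (denom > 0) {
        0.5 * proxy_cov(pr$row[i], pr$col[i]) / denom
      } else {
        0
      }
      if (val == 0 && pr$col[i] %in% spec$latents) {
        # markerless loading: break symmetry between factors with a small
        # deterministic wiggle so twin factors do not start identically
        val <- 0.3 * sqrt(proxy_var(pr$row[i])) *
          (1 + 0.25 * ((j %% 3) - 1)) *
          (if (match(pr$col[i], spec$latents) %% 2 == 0) -1 else 1)
      }
      start[j] <- val
    } else if (pr$row[i] == pr$col[i]) {
      start[j] <- 0.5 * proxy_var(pr$row[i])
    } else {
      start[j] <- 0.25 * proxy_cov(pr$row[i], pr$col[i])
    }
  }
  start
}

sem_lower_bounds <- function(spec) {
  pr <- spec$params[spec$params$free, , drop = FALSE]
  ifelse(pr$matrix == "S" & pr$row == pr$col, 1e-6, -Inf)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F_ML = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters (quasi-Newton with analytic gradient and
#' variance parameters bounded below), with marker-scaled heuristic
#' starting values and a small number of jittered restarts on
#' non-convergence. The model chi-square is `(n-1) F_ML` at the optimum
#' (`n F_ML` via `chisq_n = TRUE`); AIC is `-2 loglik + 2 q`. Standard
#' errors come from the inverse of the numerically evaluated information
#' matrix.
#'
#' @param spec a [sem_spec()].
#' @param data data frame containing all observed variables (rows =
#'   species or other sampling units).
#' @param chisq_n use `n` instead of `n - 1` as the chi-square multiplier.
#' @param max_restarts jittered restarts attempted when the optimizer
#'   reports non-convergence.
#' @return a `sem_fit` object; see [tidy.sem_fit()] and
#'   [glance.sem_fit()].
#' @export
sem_fit <- function(spec, data, chisq_n = FALSE, max_restarts = 4) {
  obs <- spec$observed
  missing_vars <- setdiff(obs, names(data))
  if (length(missing_vars)) {
    stop_validation(glue::glue(
      "data lacks observed variable(s): ",
      "{paste(missing_vars, collapse = ', ')}"
    ))
  }
  x <- as.matrix(data[, obs, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- length(obs)
  if (n <= p) {
    stop_validation("need more rows than observed variables")
  }
  s_samp <- cov(x) # denominator n - 1
  if (inherits(tryCatch(chol(s_samp), error = identity), "error")) {
    stop_validation(
      "sample covariance is not positive definite; check the variables"
    )
  }
  log_det_s <- determinant(s_samp, logarithm = TRUE)$modulus[1]
  obj <- function(th) fml_value(spec, th, s_samp, log_det_s)
  gr <- function(th) fml_gradient(spec, th, s_samp)
  lower <- sem_lower_bounds(spec)
  start <- sem_start(spec, s_samp)

  best <- NULL
  attempt <- 0
  repeat {
    st <- if (attempt == 0) start else {
      with_seed(1000 + attempt,
                start * runif(length(start), 0.5, 1.5) +
                  rnorm(length(start), 0, 0.05))
    }
    st <- pmax(st, lower + 1e-6 * (lower > -Inf))
    res <- nlminb(st, obj, gradient = gr, lower = lower,
                  control = list(iter.max = 2000, eval.max = 4000))
    cand <- list(res = res, converged = res$convergence == 0 &&
                   is.finite(res$objective) && res$objective < 1e9)
    if (is.null(best) || res$objective < best$res$objective) best <- cand
    attempt <- attempt + 1
    if (best$converged || attempt > max_restarts) break
  }
  theta <- best$res$par
  fml <- best$res$objective
  grad_norm <- sqrt(sum(gr(theta)^2))
  if (!best$converged) {
    abort(glue::glue(
      "SEM did not converge (gradient norm {signif(grad_norm, 3)})"
    ), class = "popsync_error_convergence")
  }
  q <- sem_n_free(spec)
  df <- sem_df(spec)
  mult <- if (chisq_n) n else n - 1
  chisq <- max(mult * fml, 0)
  full <- ram_full_cov(spec, theta)
  sigma <- full$G[obs, obs]
  s_ml <- s_samp * (n - 1) / n
  loglik <- -n / 2 * (p * log(2 * pi) +
                        determinant(sigma, TRUE)$modulus[1] +
                        sum(solve(sigma) * s_ml))
  hess <- tryCatch(
    stats::optimHess(theta, obj, gr),
    error = function(e) NULL
  )
  vcov <- NULL
  if (!is.null(hess)) {
    info <- mult / 2 * hess
    vcov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vcov) && any(diag(vcov) < 0)) vcov <- NULL
  }
  structure(
    list(
      spec = spec, theta = theta, n = n, s_samp = s_samp,
      fml = fml, chisq = chisq, df = df,
      pvalue = if (df > 0) pchisq(chisq, df, lower.tail = FALSE)
               else NA_real_,
      loglik = loglik, aic = -2 * loglik + 2 * q,
      vcov = vcov, full_cov = full$G, sigma = sigma,
      grad_norm = grad_norm, converged = best$converged,
      chisq_n = chisq_n
    ),
    class = "sem_fit"
  )
}

#' Standardized parameter estimates
#'
#' Path and loading coefficients are rescaled by the model-implied
#' standard deviation of the predictor over that of the outcome (latent
#' variables included); covariances become correlations and variances
#' become variance proportions.
#'
#' @param fit a `sem_fit`.
#' @return numeric vector of standardized estimates aligned with the free
#'   and fixed parameters in `fit$spec$params`.
#' @export
sem_standardize <- function(fit) {
  sds <- sqrt(diag(fit$full_cov))
  if (any(sds <= 0)) {
    stop_validation("zero implied variance; cannot standardize")
  }
  names(sds) <- spec_vars(fit)
  pr <- fit$spec$params
  est <- param_estimates(fit)
  vapply(seq_len(nrow(pr)), function(i) {
    r <- pr$row[i]
    cc <- pr$col[i]
    if (pr$matrix[i] == "A") {
      est[i] * sds[cc] / sds[r]
    } else {
      est[i] / (sds[r] * sds[cc])
    }
  }, numeric(1))
}

spec_vars <- function(fit) fit$spec$vars

param_estimates <- function(fit) {
  pr <- fit$spec$params
  est <- pr$value
  est[pr$free] <- fit$theta
  est
}

#' Variance explained for an endogenous variable
#'
#' `R^2 = 1 - residual variance / model-implied variance`. Errors for
#' exogenous variables (no incoming directed path).
#'
#' @param fit a `sem_fit`.
#' @param variable variable name (observed or latent).
#' @return scalar R-squared.
#' @export
sem_r2 <- function(fit, variable) {
  pr <- fit$spec$params
  if (!variable %in% fit$spec$vars) {
    stop_validation(glue::glue("unknown variable '{variable}'"))
  }
  incoming <- pr$matrix == "A" & pr$row == variable
  if (!any(incoming)) {
    stop_validation(glue::glue("'{variable}' is exogenous; R^2 undefined"))
  }
  est <- param_estimates(fit)
  resid_ix <- which(pr$matrix == "S" & pr$row == variable &
                      pr$col == variable)
  resid <- if (length(resid_ix)) est[resid_ix] else 0
  total <- fit$full_cov[variable, variable]
  1 - resid / total
}

r2_endogenous <- function(fit) {
  pr <- fit$spec$params
  endo <- unique(pr$row[pr$matrix == "A"])
  endo <- setdiff(endo, unlist(lapply(fit$spec$latents, function(l) {
    # indicators are endogenous too; keep them but list structural first
    NULL
  })))
  setNames(vapply(endo, function(v) sem_r2(fit, v), numeric(1)), endo)
}

#' Tidy SEM parameter estimates
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return tibble with one row per (free or fixed) parameter: `label`,
#'   `matrix`, `row`, `col`, `free`, `estimate`, `std_estimate`,
#'   `std_error`, `z`, `p_value`.
#' @export
tidy.sem_fit <- function(x, ...) {
  pr <- x$spec$params
  est <- param_estimates(x)
  se <- rep(NA_real_, nrow(pr))
  if (!is.null(x$vcov)) {
    se[pr$free] <- sqrt(pmax(diag(x$vcov), 0))
  }
  z <- est / se
  tibble(
    label = pr$label, matrix = pr$matrix, row = pr$row, col = pr$col,
    free = pr$free, estimate = est,
    std_estimate = sem_standardize(x),
    std_error = se, z = z,
    p_value = 2 * pnorm(-abs(z))
  )
}

#' One-row SEM fit summary
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return tibble with `chisq`, `df`, `p_value`, `aic`, `loglik`,
#'   `n_free`, `nobs`, `converged`.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble(
    chisq = x$chisq, df = x$df, p_value = x$pvalue, aic = x$aic,
    loglik = x$loglik, n_free = sem_n_free(x$spec), nobs = x$n,
    converged = x$converged
  )
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("SEM fit: chi-square =", round(x$chisq, digits), "on", x$df,
      "df (p =", signif(x$pvalue, digits), "), AIC =",
      round(x$aic, digits), ", n =", x$n, "\n")
  r2 <- tryCatch(r2_endogenous(x), error = function(e) NULL)
  if (length(r2)) {
    structural <- setdiff(names(r2), unlist(lapply(x$spec$latents,
      function(l) indicator_names(x$spec, l))))
    if (length(structural)) {
      cat("R^2:", paste(structural, "=",
                        round(r2[structural], digits), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

indicator_names <- function(spec, latent) {
  pr <- spec$params
  pr$row[pr$matrix == "A" & pr$col == latent & pr$row %in% spec$observed]
}

#' Standardized path diagram summary plot
#'
#' Dot-and-interval display of the standardized directed paths of a
#' fitted SEM, excluding measurement loadings.
#'
#' @param object a `sem_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sem_fit <- function(object, ...) {
  d <- tidy(object) |>
    filter(.data$matrix == "A",
           !grepl("=~", .data$label, fixed = TRUE))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$std_estimate,
                                  y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standardized path coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
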