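# profile ML criterion over uniquenesses: given psi, the optimal loadings
# come from the eigen-decomposition of psi^-1/2 R psi^-1/2, and the
# criterion is the sum over the p-k trailing eigenvalues of (e - log e - 1)
fa_ml_objective <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  e <- eigen(t(R * sc) * sc, symmetric = TRUE, only.values = TRUE)$values
  e <- e[(k + 1):length(psi)]
  sum(e - log(e)) - length(e)
}

fa_ml_gradient <- function(psi, R, k) {
  lam <- fa_ml_loadings(psi, R, k)
  g <- lam %*% t(lam) + diag(psi) - R
  diag(g) / psi^2
}

fa_ml_loadings <- function(psi, R, k) {
  sc <- 1 / sqrt(psi)
  eig <- eigen(t(R * sc) * sc, symmetric = TRUE)
  lam <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)] - 1, 0)), k)
  lam * sqrt(psi)
}

#' Maximum-likelihood factor analysis of a species-by-variable table
#'
#' Variables are standardized to the correlation scale internally;
#' uniquenesses maximize the Wishart likelihood of the observed correlation
#' matrix under the loadings-plus-uniqueness decomposition (profile
#' criterion over the uniquenesses, optimized quasi-Newton with analytic
#' gradient; loadings from the eigen-solution given the uniquenesses),
#' with a 0.005 uniqueness floor guarding against Heywood cases. Unlike
#' `stats::factanal`, the fit is available when the formal
#' exploratory-analysis degrees of freedom are negative (e.g. two factors
#' on four variables), where the solution is a well-defined optimum of the
#' bounded problem even though the model is not testable. Factors are
#' oriented so
#' each factor's largest-magnitude loading is positive, making the output
#' deterministic. Rotation is configurable; `promax` is the oblique option
#' and the default (the common choice when factors are expected to
#' correlate), `varimax` keeps factors orthogonal, `none` returns the
#' canonical unrotated solution. Single-factor fits are never rotated.
#'
#' @param data data frame of species-level observations (rows = species).
#' @param cols columns to analyze (character); default: all numeric
#'   columns.
#' @param k number of factors.
#' @param rotation `"promax"`, `"varimax"` or `"none"`.
#' @param R optional correlation matrix to fit instead of `data` (then
#'   `n_obs` must be given and no scores are produced).
#' @param n_obs number of observations behind `R`.
#' @return a `factor_solution`: list with `loadings` (p x k, pattern),
#'   `structure`, `uniquenesses`, `phi` (factor correlation, identity if
#'   orthogonal), `proportion_variance`, `scores` (n x k or `NULL`),
#'   `converged`, `rotation`, `variables`.
#' @export
fit_ml_factors <- function(data = NULL, cols = NULL, k = 2,
                           rotation = c("promax", "varimax", "none"),
                           R = NULL, n_obs = NULL) {
  rotation <- match.arg(rotation)
  if (is.null(R)) {
    stopifnot(is.data.frame(data))
    cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
    x <- as.matrix(data[, cols, drop = FALSE])
    if (nrow(x) <= ncol(x)) {
      stop_validation("need more observations than variables")
    }
    n_obs <- nrow(x)
    R <- cor(x)
  } else {
    if (is.null(n_obs)) {
      stop_validation("n_obs is required when fitting a correlation matrix")
    }
    x <- NULL
    cols <- colnames(R) %||% paste0("V", seq_len(ncol(R)))
    dimnames(R) <- list(cols, cols)
  }
  p <- length(cols)
  if (!(p >= k && k >= 1)) {
    stop_validation("need p >= k >= 1")
  }
  if (p == k) {
    stop_validation("need p > k for a factor decomposition")
  }
  fa_rot <- if (k == 1) "none" else rotation
  floor_psi <- 0.005
  starts <- list(
    pmin(pmax((1 - 0.5 * k / p) / diag(solve(R)), floor_psi), 1),
    rep(0.5, p),
    rep(0.9, p)
  )
  opt <- NULL
  for (st in starts) {
    cand <- tryCatch(
      optim(st, fa_ml_objective, fa_ml_gradient, R = R, k = k,
            method = "L-BFGS-B", lower = floor_psi, upper = 1,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    # a line-search abort on a flat ridge still counts as converged when
    # the gradient has (numerically) vanished
    interior <- cand$par > floor_psi + 1e-8 & cand$par < 1 - 1e-8
    grad_ok <- max(abs(fa_ml_gradient(cand$par, R, k)[interior]), 0) < 1e-5
    cand$ok <- cand$convergence == 0 || grad_ok
    if (is.null(opt) || (cand$ok && !isTRUE(opt$ok)) ||
        (cand$ok == isTRUE(opt$ok) && cand$value < opt$value)) {
      opt <- cand
    }
    if (isTRUE(opt$ok) && opt$convergence == 0) break
  }
  if (is.null(opt) || !isTRUE(opt$ok)) {
    abort(glue::glue(
      "factor analysis did not converge: ",
      "{if (is.null(opt)) 'optimizer failure' else opt$message %||% ''}"
    ), class = "popsync_error_convergence", last_state = opt)
  }
  psi <- opt$par
  heywood <- any(psi <= floor_psi + 1e-8)
  lam <- fa_ml_loadings(psi, R, k)
  dimnames(lam) <- list(cols, paste0("F", seq_len(k)))
  phi <- diag(k)
  if (fa_rot == "varimax" && k > 1) {
    lam <- unclass(varimax(lam)$loadings)[, , drop = FALSE]
  } else if (fa_rot == "promax" && k > 1) {
    pm <- promax(unclass(varimax(lam)$loadings)[, , drop = FALSE])
    lam <- unclass(pm$loadings)[, , drop = FALSE]
    # factor correlation implied by the promax rotation matrix
    phi <- stats::cov2cor(solve(crossprod(pm$rotmat)))
  }
  # canonical orientation: largest-|loading| positive per factor
  flip <- vapply(seq_len(k), function(j) {
    sign(lam[which.max(abs(lam[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  lam <- sweep(lam, 2, flip, `*`)
  phi <- diag(flip, k) %*% phi %*% diag(flip, k)
  structure_mat <- lam %*% phi
  uniq <- setNames(psi, cols)
  prop_var <- colSums(structure_mat^2) / p
  scores <- NULL
  if (!is.null(x)) {
    scores <- scale(x) %*% solve(R, structure_mat)
    colnames(scores) <- colnames(lam)
  }
  structure(
    list(
      loadings = lam, structure = structure_mat, uniquenesses = uniq,
      phi = phi, proportion_variance = prop_var, scores = scores,
      converged = TRUE, heywood = heywood, rotation = fa_rot,
      variables = cols, correlation = R, n_obs = n_obs,
      criterion = opt$value
    ),
    class = "factor_solution"
  )
}

#' Proportion of total variable variance explained per factor
#'
#' On the correlation scale: the sum of squared structure loadings of each
#' factor divided by the number of variables.
#'
#' @param solution a `factor_solution` from [fit_ml_factors()].
#' @return named numeric vector, one proportion per factor.
#' @export
variance_explained <- function(solution) {
  solution$proportion_variance
}

#' Regression-method factor scores
#'
#' Scores are the standardized data projected through the inverse observed
#' correlation matrix onto the structure loadings; they have mean zero by
#' construction.
#'
#' @param solution a `factor_solution` from [fit_ml_factors()].
#' @param data data frame containing the solution's variables.
#' @return n x k matrix of factor scores.
#' @export
factor_scores <- function(solution, data) {
  missing_vars <- setdiff(solution$variables, names(data))
  if (length(missing_vars)) {
    stop_validation(glue::glue(
      "data lacks variable(s): {paste(missing_vars, collapse = ', ')}"
    ))
  }
  x <- scale(as.matrix(data[, solution$variables, drop = FALSE]))
  sc <- x %*% solve(solution$correlation, solution$structure)
  colnames(sc) <- colnames(solution$loadings)
  sc
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat("ML factor analysis:", length(x$variables), "variables,",
      ncol(x$loadings), "factor(s), rotation =", x$rotation, "\n")
  cat("proportion of variance:",
      paste(round(x$proportion_variance, digits), collapse = ", "), "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Tidy a factor solution into a long loadings table
#'
#' @param x a `factor_solution`.
#' @param ... unused.
#' @return tibble with `variable`, `factor`, `loading`, `structure`,
#'   `uniqueness`.
#' @export
tidy.factor_solution <- function(x, ...) {
  k <- ncol(x$loadings)
  fac <- colnames(x$loadings) %||% paste0("F", seq_len(k))
  expand_grid(variable = x$variables, factor = fac) |>
    mutate(
      loading = as.vector(t(x$loadings)),
      structure = as.vector(t(x$structure)),
      uniqueness = rep(unname(x$uniquenesses), each = k)
    )
}

#' @export
glance.factor_solution <- function(x, ...) {
  tibble(
    n_variables = length(x$variables),
    n_factors = ncol(x$loadings),
    rotation = x$rotation,
    total_variance_explained = sum(x$proportion_variance),
    converged = isTRUE(x$converged)
  )
}

#' Loading heatmap for a factor solution
#'
#' @param object a `factor_solution`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.factor_solution <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$variable,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$loading))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
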