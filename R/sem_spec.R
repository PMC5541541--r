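#' Specify a structural equation model
#'
#' Parses a compact model syntax into a RAM (reticular action model)
#' specification:
#'
#' * `latent =~ ind1 + ind2 + ...` defines a latent variable's indicators;
#'   the first listed indicator's loading is fixed to 1 (the marker) unless
#'   an explicit coefficient such as `1*ind1` is given elsewhere.
#' * `y ~ x1 + x2` defines directed regression paths.
#' * `a ~~ b` frees the (residual) covariance between `a` and `b`;
#'   `a ~~ 0.5*b` fixes it.
#'
#' A free (residual) variance is added automatically for every variable.
#' Exogenous covariances are *not* added automatically; list them
#' explicitly. The structural graph must be recursive (no feedback loops).
#'
#' @param model model syntax string (newline- or `;`-separated lines,
#'   `#` comments allowed).
#' @return a `sem_spec`: list with `observed`, `latents`, `vars` (all
#'   variables, observed first), `params` (tibble: `matrix` ("A" or "S"),
#'   `row`, `col`, `free`, `value`, `label`) and `model` (the input
#'   string).
#' @export
sem_spec <- function(model) {
  lines <- unlist(strsplit(model, "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # join continuation lines (ending in an operator or '+')
  merged <- character(0)
  for (ln in lines) {
    if (length(merged) && grepl("(\\+|~|=~)\\s*$", merged[length(merged)])) {
      merged[length(merged)] <- paste(merged[length(merged)], ln)
    } else {
      merged <- c(merged, ln)
    }
  }
  lines <- merged

  parse_rhs <- function(rhs) {
    terms <- trimws(unlist(strsplit(rhs, "\\+")))
    map(terms, function(tm) {
      if (grepl("\\*", tm)) {
        parts <- trimws(unlist(strsplit(tm, "\\*")))
        if (identical(parts[1], "NA")) {
          # explicitly free (overrides the automatic marker fixing)
          return(list(var = parts[2], fixed = FALSE, value = NA_real_,
                      explicit_free = TRUE))
        }
        val <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(val)) {
          stop_validation(glue::glue("bad fixed coefficient in '{tm}'"))
        }
        list(var = parts[2], fixed = TRUE, value = val)
      } else {
        list(var = tm, fixed = FALSE, value = NA_real_,
             explicit_free = FALSE)
      }
    })
  }

  entries <- map(lines, function(ln) {
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
          else if (grepl("~~", ln, fixed = TRUE)) "~~"
          else if (grepl("~", ln, fixed = TRUE)) "~"
          else stop_validation(glue::glue("cannot parse line: '{ln}'"))
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_validation(glue::glue("cannot parse line: '{ln}'"))
    }
    list(lhs = trimws(parts[1]), op = op, rhs = parse_rhs(parts[2]))
  })

  latents <- unique(map_chr_(entries, function(e) {
    if (e$op == "=~") e$lhs else NA_character_
  }))
  latents <- latents[!is.na(latents)]
  mentioned <- unique(unlist(map(entries, function(e) {
    c(e$lhs, vapply(e$rhs, `[[`, character(1), "var"))
  })))
  observed <- setdiff(mentioned, latents)
  vars <- c(observed, latents)

  rows <- list()
  add <- function(matrix, row, col, free, value, label) {
    rows[[length(rows) + 1]] <<- tibble(
      matrix = matrix, row = row, col = col, free = free,
      value = value, label = label
    )
  }

  for (e in entries) {
    if (e$op == "=~") {
      for (i in seq_along(e$rhs)) {
        tm <- e$rhs[[i]]
        fixed <- tm$fixed ||
          (i == 1L && !isTRUE(tm$explicit_free))
        value <- if (tm$fixed) tm$value else if (fixed) 1 else NA_real_
        add("A", tm$var, e$lhs, !fixed, value,
            paste0(e$lhs, "=~", tm$var))
      }
    } else if (e$op == "~") {
      for (tm in e$rhs) {
        add("A", e$lhs, tm$var, !tm$fixed, tm$value,
            paste0(e$lhs, "~", tm$var))
      }
    } else {
      for (tm in e$rhs) {
        add("S", e$lhs, tm$var, !tm$fixed, tm$value,
            paste0(e$lhs, "~~", tm$var))
      }
    }
  }
  params <- list_rbind(rows)
  dup <- duplicated(params[, c("matrix", "row", "col")])
  if (any(dup)) {
    stop_validation(glue::glue(
      "duplicated parameter(s): ",
      "{paste(params$label[dup], collapse = ', ')}"
    ))
  }
  # automatic free (residual) variances
  has_var <- params$matrix == "S" & params$row == params$col
  for (v in setdiff(vars, params$row[has_var])) {
    params <- bind_rows(params, tibble(
      matrix = "S", row = v, col = v, free = TRUE, value = NA_real_,
      label = paste0(v, "~~", v)
    ))
  }
  spec <- structure(
    list(observed = observed, latents = latents, vars = vars,
         params = params, model = model),
    class = "sem_spec"
  )
  # reject non-recursive structural graphs early
  a_free <- ram_matrices(spec, rep(0.5, sem_n_free(spec)))$A
  if (any(abs(eigen(a_free, only.values = TRUE)$values) > 1e-8)) {
    ord <- topo_order(spec)
    if (is.null(ord)) {
      stop_validation("model graph contains a feedback loop (non-recursive)")
    }
  }
  spec
}

map_chr_ <- function(x, f) vapply(x, f, character(1))

topo_order <- function(spec) {
  a <- spec$params[spec$params$matrix == "A", , drop = FALSE]
  vars <- spec$vars
  edges <- unique(a[, c("row", "col")])
  ord <- character(0)
  remaining <- vars
  repeat {
    sources <- remaining[!remaining %in% edges$row[edges$col %in% remaining]]
    sources <- remaining[vapply(remaining, function(v) {
      !any(edges$row == v & edges$col %in% remaining)
    }, logical(1))]
    if (!length(sources)) {
      return(if (length(remaining)) NULL else ord)
    }
    ord <- c(ord, sources)
    remaining <- setdiff(remaining, sources)
    if (!length(remaining)) {
      return(ord)
    }
  }
}

sem_n_free <- function(spec) sum(spec$params$free)

#' Model degrees of freedom of a SEM specification
#'
#' `p(p+1)/2` observed covariance moments minus the number of free
#' parameters.
#'
#' @param spec a `sem_spec`.
#' @return integer degrees of freedom.
#' @export
sem_df <- function(spec) {
  p <- length(spec$observed)
  as.integer(p * (p + 1) / 2 - sem_n_free(spec))
}

# assemble A and S (all-variables order) from a free-parameter vector
ram_matrices <- function(spec, theta) {
  m <- length(spec$vars)
  a <- matrix(0, m, m, dimnames = list(spec$vars, spec$vars))
  s <- a
  pr <- spec$params
  vals <- pr$value
  vals[pr$free] <- theta
  for (i in seq_len(nrow(pr))) {
    if (pr$matrix[i] == "A") {
      a[pr$row[i], pr$col[i]] <- vals[i]
    } else {
      s[pr$row[i], pr$col[i]] <- vals[i]
      s[pr$col[i], pr$row[i]] <- vals[i]
    }
  }
  list(A = a, S = s)
}

# full covariance over all variables: (I-A)^-1 S (I-A)^-T
ram_full_cov <- function(spec, theta) {
  ms <- ram_matrices(spec, theta)
  m <- length(spec$vars)
  b <- tryCatch(solve(diag(m) - ms$A),
                error = function(e) {
                  stop_validation("(I - A) is singular (non-recursive misuse)")
                })
  list(G = b %*% ms$S %*% t(b), B = b, S = ms$S, A = ms$A)
}

#' Model-implied covariance matrix of the observed variables
#'
#' RAM formulation: the observed block of
#' `(I - A)^-1 S (I - A)^-T`, where `A` holds directed paths and loadings
#' and `S` the symmetric (co)variances.
#'
#' @param spec a `sem_spec`.
#' @param theta numeric vector of free-parameter values, in the order of
#'   `spec$params[spec$params$free, ]`.
#' @return implied covariance matrix over `spec$observed`.
#' @export
implied_sigma <- function(spec, theta) {
  g <- ram_full_cov(spec, theta)$G
  g[spec$observed, spec$observed, drop = FALSE]
}

#' Simulate observations from a SEM specification
#'
#' Draws multivariate normal data with the model-implied covariance
#' (zero means).
#'
#' @param spec a `sem_spec`.
#' @param theta free-parameter values.
#' @param n number of rows.
#' @param seed optional seed.
#' @return tibble with `spec$observed` columns.
#' @export
sem_simulate <- function(spec, theta, n, seed = NULL) {
  sigma <- implied_sigma(spec, theta)
  r <- chol(sigma)
  with_seed(seed, {
    z <- matrix(rnorm(n * ncol(sigma)), n)
    as_tibble(as.data.frame(z %*% r))
  })
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("SEM specification:", length(x$observed), "observed,",
      length(x$latents), "latent variable(s);",
      sem_n_free(x), "free parameters, df =", sem_df(x), "\n")
  invisible(x)
}
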