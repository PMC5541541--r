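# shared internal helpers

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never perturb the
#' caller's random-number stream. All stochastic stages route their draws
#' through this helper so a master seed propagates deterministically.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed (< 2^31) from a master seed and a stage label;
# deterministic, so per-species / per-stage streams are reproducible and
# independent of execution order
derive_seed <- function(seed, ...) {
  if (is.null(seed)) {
    return(NULL)
  }
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483587
  as.integer((h + as.integer(seed)) %% 2147483587 + 1)
}

# z-score a vector; errors if fewer than 2 distinct finite values
zscore <- function(x, allow_constant = FALSE) {
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) {
      return(rep(0, length(x)))
    }
    abort("cannot z-score a constant (or length-1) series",
      class = "popsync_error_degenerate"
    )
  }
  (x - m) / s
}

# stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x < 18
  out[small] <- log1p(exp(x[small]))
  mid <- !small & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "popsync_error_schema", ...)
}

stop_integrity <- function(msg, ...) {
  abort(msg, class = "popsync_error_integrity", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "popsync_error_validation", ...)
}

`%||%` <- rlang::`%||%`
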