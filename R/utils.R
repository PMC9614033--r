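#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pt rnorm rpois runif kmeans sd
#' @importFrom utils head tail
NULL

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_config("configuration error: '%s' must be a single integer >= %d (got %s)",
                name, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || (strict && x <= 0) || (!strict && x < 0)) {
    stop_config("configuration error: '%s' must be a %s number (got %s)",
                name, if (strict) "positive" else "non-negative", paste(format(x), collapse = ","))
  }
  as.numeric(x)
}

# Unit-normalize the rows of a 3-column matrix.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}
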