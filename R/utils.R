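# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All generators route their randomness through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

# Collect multiple validation messages and raise them all at once.
check_all <- function(checks) {
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad)) {
    stop_domain("invalid configuration:\n", paste0("  - ", bad, collapse = "\n"))
  }
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
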