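# Internal helpers shared across the acoustic and visual pipelines.

# Validate a scalar numeric argument, naming the offending field on failure.
check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", field),
         call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, field, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must lie in %s", field,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

#' Derive a child seed from a base seed and a stream index
#'
#' Keeps the result inside 32-bit integer range so `set.seed()` accepts
#' it; used to give every scene, call and sampling step of a benchmark
#' its own deterministic stream.
#'
#' @param seed Base integer seed.
#' @param index Stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  (as.integer(seed) * 1009L + as.integer(index) * 7919L) %% 2147483647L
}

db_to_linear <- function(db) 10^(db / 20)
linear_to_db <- function(x) 20 * log10(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
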