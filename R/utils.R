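# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic seed-stream derivation so that ensembles are reproducible
#' and order-independent: molecule i always receives the same seed
#' regardless of how many molecules are simulated. Uses MINSTD-style
#' modular arithmetic; all intermediates stay below 2^53 so the double
#' arithmetic is exact, and the result is always a valid 32-bit seed.
#'
#' @param seed master seed (non-negative integer below 2^31).
#' @param ... one or more integer keys (e.g. molecule index, stream id).
#' @return an integer in `[1, 2147483646]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

# robust sd via median absolute deviation
robust_sd <- function(x) stats::mad(x, constant = 1.4826)
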