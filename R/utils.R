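# Internal helpers shared across modules.

# Deterministic per-stream seed derivation so that, e.g., the state and
# injury draws of one scenario are independently reproducible. Kept within
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, stream, index = 0L) {
  stream_id <- switch(stream,
    states = 1L, injuries = 2L, power = 3L, grid = 4L, matched = 5L,
    abort(paste0("unknown RNG stream '", stream, "'"))
  )
  mix <- (as.numeric(seed) * 48271 + stream_id * 9631 + as.numeric(index) * 127) %%
    2147483399
  as.integer(mix) + 1L
}

#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used in the injury-rate
#' and recruitment descriptives (base R's `round()` rounds half to even,
#' which would turn 0.25 per 1000 into 0.2 rather than 0.3).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(c(1.05, 2.5, -2.5), c(1, 0, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s (got %s)",
                  field, min, deparse(x)))
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open_hi = FALSE,
                           open_lo = FALSE) {
  bad <- length(x) != 1 || !is.finite(x) || x < lo || x > hi ||
    (open_hi && x >= hi) || (open_lo && x <= lo)
  if (bad) {
    abort(sprintf("`%s` must lie in %s%s, %s%s (got %s)", field,
                  if (open_lo) "(" else "[", format(lo), format(hi),
                  if (open_hi) ")" else "]", deparse(x)))
  }
  as.numeric(x)
}

check_positive <- function(x, field) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number (got %s)",
                  field, deparse(x)))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
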