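#' Round half away from zero
#'
#' Reporting in this package follows the usual clinical-physics convention of
#' rounding halves away from zero (so 0.125 at 2 decimals is 0.13), unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a child RNG seed from a base seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
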