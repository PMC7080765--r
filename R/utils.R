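#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1 at one digit), the
#' convention used when reporting chip summary tables; base `round()`
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(2.345, 2)  # 2.35
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## internal: stop with a consistent prefix
chk <- function(cond, ...) if (!cond) stop(..., call. = FALSE)

## internal: deterministic seed derivation for sub-streams, kept < 2^31
subSeed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + k
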