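#' Round half away from zero
#'
#' Decimal rounding with halves going up (0.455 -> 0.46 at 2 digits), the
#' convention used for printed ratios, unlike base \code{round}'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# derive a stream seed from a master seed, staying inside 32-bit range
.deriveSeed <- function(seed, k) {
  (as.numeric(seed) + 1000003 * k) %% 2147483647
}
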