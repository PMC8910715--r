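#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages and Mb
#' spans here use conventional half-up rounding instead (43.155 -> 43.16).
#'
#' @param x numeric vector (non-negative use intended).
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
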