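#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; composition percentages are
#' reported with conventional half-up rounding so that printed tables are
#' reproduced digit for digit.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Derive a child seed from a master seed; keeps results < 2^31 so they are
# valid R integer seeds.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Lower-triangle vector of a square matrix / dist object, in dist order.
lower_tri <- function(m) {
  m <- as.matrix(m)
  m[lower.tri(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
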