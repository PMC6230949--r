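# Haldane map function: crossovers are Poisson with no interference, so
# the genetic distance between two loci with recombination fraction r is
# d = -50 ln(1 - 2r) centimorgans, and conversely r = (1 - e^{-d/50})/2.

#' Haldane map distance from a recombination fraction
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance(s) in centimorgans.
#' @seealso [haldane_r()] for the inverse.
#' @export
haldane_cm <- function(r) {
  assert_that(is.numeric(r) && all(is.finite(r)), "r must be finite numeric")
  assert_that(all(r >= 0 & r < 0.5), "r must lie in [0, 0.5)")
  -50 * log1p(-2 * r)
}

#' Recombination fraction from a Haldane map distance
#'
#' @param d Genetic distance(s) in centimorgans, `d >= 0`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d) {
  assert_that(is.numeric(d) && all(d >= 0), "d must be non-negative")
  -0.5 * expm1(-d / 50)
}
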