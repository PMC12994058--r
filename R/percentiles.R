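#' Linear-interpolation percentile
#'
#' Percentile of a numeric sample by sorted linear interpolation with
#' inclusive endpoints: `p = 0` returns the minimum, `p = 100` the maximum,
#' and interior percentiles interpolate linearly between the order
#' statistics at fractional rank `1 + (n - 1) p / 100`. This is the single
#' percentile definition used everywhere a threshold is derived from a
#' reference distribution (behavioral cuts, sleep scores, activation
#' scores), so every cut in a threshold audit can be replayed exactly.
#'
#' @param x numeric vector; non-finite values are dropped.
#' @param p percentile in `[0, 100]`; may be a vector.
#' @return numeric vector of the same length as `p`.
#' @examples
#' pctl(c(1, 2, 3, 4, 5), 50)   # 3
#' pctl(c(1, 2, 3, 4), c(0, 100))
#' @export
pctl <- function(x, p) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    stop("pctl(): no finite values to take a percentile of")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("pctl(): 'p' must lie in [0, 100]")
  x <- sort(x)
  n <- length(x)
  h <- 1 + (n - 1) * p / 100
  lo <- pmin(floor(h), n)
  hi <- pmin(lo + 1, n)
  frac <- h - lo
  unname(x[lo] * (1 - frac) + x[hi] * frac)
}
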