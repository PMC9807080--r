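#' Mean-center a numeric vector
#'
#' Subtracts the sample mean of the non-missing values. Used to build the
#' deprivation-by-income interaction terms of the moderation analysis, where
#' both interacting variables are centered before the product is formed.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @return Numeric vector of the same length with mean 0 (within 1e-12).
#' @examples
#' center(c(1, 2, 3))
#' @export
center <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  m <- mean(x, na.rm = TRUE)
  if (is.na(m)) abort("`x` has no non-missing values to center on.")
  x - m
}

# z-score with sample SD; constant input maps to 0 rather than NaN
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

# unbiased stochastic rounding: E[dither_round(x)] == x away from the clip
# boundaries, because round(x + U(-.5, .5)) hits floor(x)/ceiling(x) with
# exactly the interpolating probabilities
dither_round <- function(x, lo, hi) {
  pmin(pmax(round(x + runif(length(x), -0.5, 0.5)), lo), hi)
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  invisible(x)
}
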