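# Circular (hue) helpers.  Hue lives on [0, 360); red/orange hues straddle
# the 0/360 boundary, so all averaging and interpolation is done on the
# circle.

#' Circular mean of angles in degrees
#'
#' @param deg numeric vector of angles in degrees.
#' @param w optional non-negative weights.
#' @return Mean direction in `[0, 360)`; `NaN` if the resultant is zero.
#' @export
circular_mean <- function(deg, w = NULL) {
  rad <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  s <- sum(w * sin(rad)); c <- sum(w * cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12 * sum(w)) return(NaN)
  (atan2(s, c) * 180 / pi) %% 360
}

#' Shortest angular difference between two hues
#'
#' @param a,b hues in degrees.
#' @return `min(|a - b|, 360 - |a - b|)`, in `[0, 180]`.
#' @export
hue_difference <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# signed shortest arc from `from` towards `to`, in (-180, 180]
hue_signed_arc <- function(from, to) {
  ((to - from + 180) %% 360) - 180
}

# interpolate along the shortest arc: t = 0 -> from, t = 1 -> to
hue_lerp <- function(from, to, t) {
  (from + t * hue_signed_arc(from, to)) %% 360
}

# draw from a wrapped normal on the hue circle
rwrapped_hue <- function(n, mean, sd) (rnorm(n, mean, sd)) %% 360
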