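#' Wrap angles in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

## wrap to (-90, 90]: distance helper for phases restricted modulo 180
wrap_half_deg <- function(x) {
  w <- x %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

#' Intensity-weighted circular phase statistics
#'
#' Computes the weighted circular mean of a set of phases and the weighted
#' standard deviation of the wrapped deviations about that mean. Phases are in
#' degrees; weights must be non-negative and not all zero.
#'
#' @param phases numeric vector of phases in degrees.
#' @param weights non-negative weights (e.g. pixel intensities).
#' @return list with elements `mean` and `sd`, both in degrees.
#' @examples
#' weighted_phase_stats(c(350, 10), c(1, 1))  # mean 0, sd 10
#' @export
weighted_phase_stats <- function(phases, weights = rep(1, length(phases))) {
  stopifnot(length(phases) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (!(sw > 0)) stop("sum of weights must be positive")
  z <- sum(weights * exp(1i * phases * pi / 180)) / sw
  m <- Arg(z) * 180 / pi
  d <- wrap_deg(phases - m)
  list(mean = wrap_deg(m), sd = sqrt(sum(weights * d^2) / sw))
}

circ_mean_deg <- function(phases, weights = rep(1, length(phases))) {
  weighted_phase_stats(phases, weights)$mean
}

## smallest 5-smooth integer >= n (keeps FFT grids fast)
next_smooth <- function(n) {
  n <- max(1L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via a random unit quaternion
#' (uses the current RNG state).
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
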