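#' Preferred values of a ring layer
#'
#' Unit preferred colors, evenly spaced on `[0, 2*pi)`.
#'
#' @param n_units number of units on the ring (default 20).
#' @return numeric vector of length `n_units`, in radians.
#' @export
preferred_values <- function(n_units = 20) {
  2 * pi * (seq_len(n_units) - 1) / n_units
}

#' Shortest signed circular difference in radians
#' @param a,b angles in radians.
#' @return signed difference `a - b` wrapped into `(-pi, pi]`.
#' @keywords internal
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d - 2 * pi * (d > pi)
}

#' Encode a color as a Gaussian population bump
#'
#' Each unit on the ring responds maximally to its preferred color; a
#' presented color produces a circular-Gaussian profile of activity over the
#' layer. With the default width roughly 10 of 20 units exceed activity 0.1,
#' the coarse-coding regime used throughout the circuit.
#'
#' @param theta color in radians (any finite value; wrapped onto the circle).
#' @param width circular-Gaussian sigma in radians (default 0.72).
#' @param n_units ring size (default 20; must be at least 4).
#' @return numeric activity vector of length `n_units`, peak value 1.
#' @export
encode_color <- function(theta, width = 0.72, n_units = 20) {
  if (!is.finite(theta) || width <= 0)
    stop("encode_color: theta must be finite and width positive")
  if (n_units < 4) stop("encode_color: need at least 4 units on the ring")
  d <- circ_diff(preferred_values(n_units), theta)
  exp(-d^2 / (2 * width^2))
}

#' Population-vector decode of ring activity
#'
#' Decodes a color estimate as the angle of the activity-weighted resultant
#' vector `sum_k y_k exp(i pref_k)`. The normalized resultant length acts as
#' a confidence: near 0 for silent, uniform, or symmetric-bimodal activity.
#'
#' @param activities nonnegative activity vector over the ring.
#' @param floor resultant-length floor below which the activity is flagged
#'   non-decodable (used for non-response detection); default 0.05.
#' @return list with `theta` (radians in `[0, 2*pi)`, `NA` if non-decodable),
#'   `resultant` (normalized resultant length in `[0, 1]`), and `decodable`.
#' @export
decode_color <- function(activities, floor = 0.05) {
  if (any(activities < 0)) stop("decode_color: negative activities")
  n <- length(activities)
  basis <- ring_basis(n)
  tot <- sum(activities)
  if (tot <= 0) {
    return(list(theta = NA_real_, resultant = 0, decodable = FALSE))
  }
  zx <- sum(activities * basis$cosp) / tot
  zy <- sum(activities * basis$sinp) / tot
  r <- sqrt(zx^2 + zy^2)
  if (r < floor) {
    return(list(theta = NA_real_, resultant = r, decodable = FALSE))
  }
  list(theta = atan2(zy, zx) %% (2 * pi), resultant = r, decodable = TRUE)
}

# cached cos/sin tables of the preferred values, keyed by ring size
.ring_basis_cache <- new.env(parent = emptyenv())
ring_basis <- function(n) {
  key <- as.character(n)
  b <- .ring_basis_cache[[key]]
  if (is.null(b)) {
    pref <- preferred_values(n)
    b <- list(cosp = cos(pref), sinp = sin(pref))
    .ring_basis_cache[[key]] <- b
  }
  b
}

#' Signed circular report error in degrees
#'
#' Shortest signed angular difference `reported - target`, in degrees on
#' `(-180, 180]`; a tie at half a circle maps to +180.
#'
#' @param reported,target angles in radians.
#' @return signed error in degrees.
#' @export
circular_error <- function(reported, target) {
  stopifnot(all(is.finite(reported)), all(is.finite(target)))
  d <- circ_diff(reported, target) * 180 / pi
  ifelse(d <= -180, 180, d)
}
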