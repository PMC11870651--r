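#' Generate one color-wheel episode
#'
#' An episode is a sequence of store trials (each pairing a uniform random
#' color on `[0, 2*pi)` with a distinct discrete orientation) followed by one
#' recall probe of a uniformly chosen presented orientation. The set size
#' bounds the number of items presented before recall. Episodes are drawn
#' from the current RNG state, so identical seeds give identical episodes.
#'
#' @param set_size number of items, between 2 and `n_orient`.
#' @param n_orient number of discrete orientations available; defaults to
#'   the set size (each condition's orientation inventory matches the
#'   number of items it must bind, so every episode presents all of them).
#' @param n_store number of store trials this episode (default `set_size`;
#'   may be smaller to present fewer items than the maximum).
#' @return data.frame of class `episode` with one row per trial and columns
#'   `trial`, `kind` (store/recall), `orientation`, `color` (radians, `NA` on
#'   recall), `target` (the color to report: the presented color on store
#'   trials, the probed item's stored color on recall).
#' @export
gen_episode <- function(set_size, n_orient = set_size, n_store = set_size) {
  if (set_size < 2) stop("set_size must be at least 2")
  if (set_size > n_orient)
    stop("set_size cannot exceed the number of orientations (", n_orient, ")")
  stopifnot(n_store >= 1, n_store <= set_size)
  orientations <- sample.int(n_orient, n_store)
  colors <- stats::runif(n_store, 0, 2 * pi)
  probe_idx <- sample.int(n_store, 1)
  ep <- data.frame(
    trial = seq_len(n_store + 1L),
    kind = c(rep("store", n_store), "recall"),
    orientation = c(orientations, orientations[probe_idx]),
    color = c(colors, NA_real_),
    target = c(colors, colors[probe_idx])
  )
  attr(ep, "set_size") <- set_size
  attr(ep, "probe_lag") <- n_store + 1L - probe_idx
  class(ep) <- c("episode", "data.frame")
  ep
}

#' Score a recall response
#'
#' A non-response is scored by substituting a uniform random report (drawn
#' from the current RNG state), mimicking random guessing; otherwise the
#' signed circular error of the report is taken directly. Reward is the
#' linear closeness rule of [compute_reward()].
#'
#' @param reported reported color in radians (ignored when `non_response`).
#' @param non_response logical flag.
#' @param target probed item's true color in radians.
#' @param reward_span closeness threshold in degrees.
#' @return list with `error_deg` (signed) and `reward`.
#' @export
score_recall <- function(reported, non_response, target, reward_span = 45) {
  if (non_response) reported <- stats::runif(1, 0, 2 * pi)
  err <- circular_error(reported, target)
  list(error_deg = err,
       reward = 1 - abs(err) / reward_span)
}

#' Out-of-cluster variance of the non-probed items
#'
#' Circular spread, in degrees, of the colors of the items that were *not*
#' probed: low OCV means the other items are similar and hence chunkable.
#' Computed as the circular standard deviation `sqrt(-2 log R) * 180/pi`,
#' where R is the mean resultant length of the other items' colors.
#'
#' @param colors colors of all items in the episode (radians).
#' @param probed_index index of the probed item within `colors`.
#' @return OCV in degrees, or `NA` (flagged undefined) when fewer than two
#'   other items exist.
#' @export
ocv <- function(colors, probed_index) {
  others <- colors[-probed_index]
  if (length(others) < 2) return(NA_real_)
  R <- sqrt(mean(cos(others))^2 + mean(sin(others))^2)
  R <- min(R, 1)
  if (R <= 0) return(Inf)
  sqrt(-2 * log(R)) * 180 / pi
}
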