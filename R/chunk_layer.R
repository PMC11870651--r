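#' Chunk-layer specification
#'
#' The chunk layer is a posterior ring-attractor layer receiving convergent
#' excitation from the sensory input layer (bottom-up, strong) and from each
#' PFC maintenance stripe (top-down, weaker). When the current input overlaps
#' a maintained representation, the convergent excitation merges the two into
#' one attractor biased toward the overlap; lateral (FFFB) inhibition
#' suppresses more distant maintained bumps, so only the nearest neighbor
#' attracts. The bottom-up : top-down scale ratio (default 1 : 0.5) and the
#' inhibition jointly set how close items must be to chunk; the defaults put
#' the peak of the attraction profile at an intermediate (~60 degree) offset.
#'
#' @param input_scale relative scale of the sensory projection.
#' @param pfc_scale relative scale of each top-down PFC projection; must be
#'   smaller than `input_scale` so the layer preferentially mirrors the input.
#' @param n_pfc number of configured top-down projections (one per stripe);
#'   enters the static normalization of the scale-weighted average so layer
#'   gain does not jump when stripes empty or fill.
#' @param n_units ring size.
#' @param kernel_width circular-Gaussian width (radians) of the fixed
#'   topographic weights of both projections.
#' @param unit a [unit_params()] for the chunk-layer neurons.
#' @param inhib an [inhib_params()] for the chunk-layer pool.
#' @param n_cycles settling cycle budget.
#' @return An object of class `chunk_spec`.
#' @export
chunk_spec <- function(input_scale = 1, pfc_scale = 0.5, n_pfc = 2,
                       n_units = 20, kernel_width = 0.45,
                       unit = unit_params(), inhib = inhib_params(Gi = 2.2),
                       n_cycles = 50) {
  stopifnot(input_scale > pfc_scale, pfc_scale > 0, n_pfc >= 1)
  structure(list(input_scale = input_scale, pfc_scale = pfc_scale,
                 n_pfc = n_pfc, n_units = n_units,
                 kernel_width = kernel_width, unit = unit, inhib = inhib,
                 n_cycles = n_cycles,
                 kernel = ring_kernel(n_units, kernel_width)),
            class = "chunk_spec")
}

#' Fixed topographic ring-to-ring weight matrix
#'
#' Circular-Gaussian weight profile: unit `i` of the sender connects most
#' strongly to unit `i` of the receiver, falling off with circular distance.
#'
#' @param n_units ring size.
#' @param width Gaussian sigma in radians.
#' @return `n_units x n_units` weight matrix with unit diagonal.
#' @export
ring_kernel <- function(n_units = 20, width = 0.72) {
  pref <- preferred_values(n_units)
  d <- outer(pref, pref, circ_diff)
  exp(-d^2 / (2 * width^2))
}

#' Settle the chunk layer on one stimulus
#'
#' Runs the chunk-layer dynamics with the sensory bump clamped bottom-up and
#' the currently maintained PFC bumps clamped top-down, and returns the
#' settled activity. With no (or only distant) maintained content the settled
#' bump decodes to the sensory value; with a sufficiently close maintained
#' bump it decodes to a merged value pulled from the sensory input toward the
#' nearest PFC representation.
#'
#' @param sensory sensory bump (activity vector of length `spec$n_units`).
#' @param pfc_maintained list (possibly empty) of maintained PFC bumps; empty
#'   stripes may be passed as zero vectors.
#' @param spec a [chunk_spec()].
#' @return list as returned by [settle()].
#' @export
chunk_settle <- function(sensory, pfc_maintained = list(), spec = chunk_spec()) {
  stopifnot(length(sensory) == spec$n_units)
  total_rel <- spec$input_scale + spec$pfc_scale * spec$n_pfc
  K <- spec$kernel
  n <- spec$n_units
  ge <- spec$input_scale * as.vector(crossprod(K, sensory)) / n
  for (p in pfc_maintained) {
    stopifnot(length(p) == n)
    ge <- ge + spec$pfc_scale * as.vector(crossprod(K, p)) / n
  }
  ge <- ge / total_rel
  settle_ge(ge, spec)
}

# settle from a precomputed ge vector (fast path shared with chunk_settle and
# the response layer; compiled core). The rate code depends on ge and the
# pooled gi only, so the membrane potential is not tracked here (see settle()
# for the full state).
settle_ge <- function(ge, spec) {
  unit <- spec$unit; inhib <- spec$inhib
  ff <- inhib$ff_gain * max(0, mean(ge) - inhib$ff_floor)
  # ge_theta(gi) = a * gi + b is linear in the pooled inhibition
  a <- unit$gbar_i * (unit$E_i - unit$Theta) / (unit$Theta - unit$E_e)
  b <- unit$gbar_l * (unit$E_l - unit$Theta) / (unit$Theta - unit$E_e)
  res <- .settle_ge_core(ge, unit$gbar_e, unit$gamma, a, b, inhib$Gi, ff,
                         inhib$fb_gain, inhib$fb_tau, spec$n_cycles, 1e-4)
  res$ge <- ge
  res
}

#' Chunking profile: attraction as a function of similarity
#'
#' Places a single maintained PFC bump at each angular offset from a fixed
#' sensory value, settles the chunk layer, and reports the deviation of the
#' decoded chunk representation from the sensory value (positive = toward the
#' PFC bump). The profile is zero at zero offset, rises to a single interior
#' peak where merging occurs, and returns toward zero at large offsets where
#' lateral inhibition suppresses the distant bump and the layer mirrors the
#' input.
#'
#' @param delta_grid angular offsets in degrees (e.g. `seq(0, 180, by = 5)`).
#' @param spec a [chunk_spec()].
#' @param theta sensory color used for the sweep (radians).
#' @return data.frame with columns `offset_deg` and `deviation_deg`.
#' @export
chunking_profile <- function(delta_grid = seq(0, 180, by = 5),
                             spec = chunk_spec(), theta = pi / 2) {
  sensory <- encode_color(theta, n_units = spec$n_units)
  dev <- vapply(delta_grid, function(off) {
    pfc <- encode_color(theta + off * pi / 180, n_units = spec$n_units)
    out <- chunk_settle(sensory, list(pfc), spec)
    dec <- decode_color(out$y)
    if (!dec$decodable) return(NA_real_)
    circular_error(dec$theta, theta)
  }, numeric(1))
  data.frame(offset_deg = delta_grid, deviation_deg = dev)
}
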