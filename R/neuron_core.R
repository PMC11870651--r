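#' Rate-coded point-neuron parameters
#'
#' Biophysical constants for the rate-coded point neurons used throughout the
#' circuit. Membrane potential integrates excitatory, inhibitory, and leak
#' currents toward their conductance-weighted equilibrium; the rate code is a
#' thresholded saturating function of the excess excitatory conductance.
#' Defaults follow standard published Leabra-style values (normalized
#' potentials: inhibitory reversal 0.25, leak/rest 0.3, threshold 0.5,
#' excitatory reversal 1).
#'
#' @param Cm membrane capacitance; with `dt` sets the integration rate
#'   constant (`dt/Cm` per cycle).
#' @param E_e,E_i,E_l excitatory / inhibitory / leak reversal potentials,
#'   normalized units. Must satisfy `E_i <= E_l < Theta < E_e`.
#' @param gbar_e,gbar_i,gbar_l maximal conductances (dimensionless
#'   multipliers on the time-varying conductance fractions).
#' @param Theta firing threshold potential.
#' @param gamma activation gain of the rate function.
#' @return An object of class `unit_params`.
#' @export
unit_params <- function(Cm = 1, E_e = 1, E_i = 0.25, E_l = 0.3,
                        gbar_e = 1, gbar_i = 1, gbar_l = 0.1,
                        Theta = 0.5, gamma = 60) {
  stopifnot(E_i <= E_l, E_l < Theta, Theta < E_e,
            gbar_e >= 0, gbar_i >= 0, gbar_l >= 0,
            gamma > 0, Cm > 0)
  structure(list(Cm = Cm, E_e = E_e, E_i = E_i, E_l = E_l,
                 gbar_e = gbar_e, gbar_i = gbar_i, gbar_l = gbar_l,
                 Theta = Theta, gamma = gamma),
            class = "unit_params")
}

#' Pooled FFFB inhibition parameters
#'
#' Layer inhibition is a single pooled conductance
#' `gi = Gi * (ff + fb)`: feedforward inhibition `ff` tracks the mean net
#' (excitatory) input to the layer above a floor, and feedback inhibition `fb`
#' tracks the layer's own mean firing rate through a single-cycle exponential
#' average (the averaging damps inhibitory oscillation in small layers).
#'
#' @param Gi overall inhibitory gain.
#' @param ff_gain feedforward coefficient.
#' @param fb_gain feedback coefficient.
#' @param ff_floor net-input floor below which the feedforward term is zero.
#' @param fb_tau exponential-average rate for the feedback term, in (0, 1];
#'   1 means no averaging.
#' @return An object of class `inhib_params`.
#' @export
inhib_params <- function(Gi = 1.6, ff_gain = 1, fb_gain = 0.6,
                         ff_floor = 0.01, fb_tau = 0.5) {
  stopifnot(Gi >= 0, ff_gain >= 0, fb_gain >= 0, ff_floor >= 0,
            fb_tau > 0, fb_tau <= 1)
  structure(list(Gi = Gi, ff_gain = ff_gain, fb_gain = fb_gain,
                 ff_floor = ff_floor, fb_tau = fb_tau),
            class = "inhib_params")
}

#' A weighted projection between layers
#'
#' @param weights matrix (senders x receivers) with entries in `[0, 1]`.
#' @param rel_scale relative strength of this projection when several
#'   converge on the same layer; contributions are combined as a
#'   scale-weighted average so that `rel_scale` only matters relative to the
#'   other converging projections.
#' @param plastic logical flag, purely informational bookkeeping here.
#' @return An object of class `projection`.
#' @export
projection <- function(weights, rel_scale = 1, plastic = FALSE) {
  weights <- as.matrix(weights)
  stopifnot(all(is.finite(weights)), all(weights >= 0), all(weights <= 1),
            rel_scale > 0)
  structure(list(weights = weights, rel_scale = rel_scale, plastic = plastic),
            class = "projection")
}

#' Net excitatory conductance from converging projections
#'
#' Each projection contributes the average of sender activity times weight
#' (`<x_i w_i>` over its senders); contributions from several projections are
#' combined as a `rel_scale`-weighted average, so a projection with twice the
#' relative scale has twice the influence on the receiving layer.
#'
#' @param sender_activities a numeric vector (single projection) or a list of
#'   numeric vectors, one per projection, activities in `[0, 1]`.
#' @param projections a [projection()] or list of them, matching
#'   `sender_activities`.
#' @param total_rel optional fixed normalizer for the scale-weighted average;
#'   defaults to the sum of the supplied `rel_scale`s. Passing the sum over a
#'   *configured* set of projections keeps the gain static when some senders
#'   are silent.
#' @return numeric vector of excitatory conductance fractions per receiving
#'   unit.
#' @export
net_excitation <- function(sender_activities, projections, total_rel = NULL) {
  if (inherits(projections, "projection")) projections <- list(projections)
  if (is.numeric(sender_activities)) sender_activities <- list(sender_activities)
  stopifnot(length(sender_activities) == length(projections),
            length(projections) >= 1)
  rels <- vapply(projections, function(p) p$rel_scale, numeric(1))
  if (is.null(total_rel)) total_rel <- sum(rels)
  n_recv <- ncol(projections[[1]]$weights)
  ge <- numeric(n_recv)
  for (k in seq_along(projections)) {
    x <- sender_activities[[k]]
    w <- projections[[k]]$weights
    if (length(x) != nrow(w))
      stop("net_excitation: ", length(x), " sender activities but weight matrix has ",
           nrow(w), " rows")
    if (ncol(w) != n_recv)
      stop("net_excitation: converging projections disagree on receiver count")
    stopifnot(all(x >= 0), all(x <= 1))
    ge <- ge + rels[k] * as.vector(crossprod(w, x)) / nrow(w)
  }
  ge / total_rel
}

#' Threshold excitatory conductance
#'
#' The excitatory conductance that would put the equilibrium membrane
#' potential exactly at the firing threshold, given the current inhibition
#' and leak.
#'
#' @param gi inhibitory conductance fraction (scalar or vector).
#' @param params a [unit_params()].
#' @return threshold conductance `ge_theta` (same shape as `gi`).
#' @export
ge_theta <- function(gi, params) {
  (gi * params$gbar_i * (params$E_i - params$Theta) +
     params$gbar_l * (params$E_l - params$Theta)) / (params$Theta - params$E_e)
}

#' Rate-code activation function
#'
#' `y = 1 / (1 + 1/(gamma * [ge - ge_theta]+))`: zero at or below the
#' threshold conductance, saturating toward 1 for strong drive, nondecreasing
#' in `ge` and nonincreasing in `gi` (inhibition raises the threshold).
#'
#' @param ge excitatory conductance fraction(s), `>= 0`.
#' @param gi inhibitory conductance fraction(s), `>= 0`.
#' @param params a [unit_params()].
#' @return activation(s) in `[0, 1)`.
#' @export
unit_activation <- function(ge, gi, params) {
  excess <- pmax(0, ge * params$gbar_e - ge_theta(gi, params))
  ifelse(excess > 0, 1 / (1 + 1 / (params$gamma * excess)), 0)
}

#' One Euler step of the membrane-potential equation
#'
#' `Cm dVm/dt = ge gbar_e (E_e - Vm) + gi gbar_i (E_i - Vm) + gbar_l (E_l - Vm)`.
#' With constant conductances Vm converges monotonically to the
#' conductance-weighted mean of the reversal potentials and is always bounded
#' by them.
#'
#' @param vm current membrane potential(s).
#' @param ge,gi excitatory / inhibitory conductance fraction(s).
#' @param params a [unit_params()].
#' @param dt Euler time step; `dt/Cm` should be at most ~0.3 per cycle for
#'   stable settling at these conductance scales.
#' @return updated membrane potential(s).
#' @export
step_membrane <- function(vm, ge, gi, params, dt = 0.3) {
  stopifnot(dt > 0)
  ge <- pmax(0, ge); gi <- pmax(0, gi)
  dvm <- ge * params$gbar_e * (params$E_e - vm) +
    gi * params$gbar_i * (params$E_i - vm) +
    params$gbar_l * (params$E_l - vm)
  vm + (dt / params$Cm) * dvm
}

#' Equilibrium membrane potential for fixed conductances
#' @inheritParams step_membrane
#' @return fixed-point Vm of the membrane equation.
#' @export
vm_equilibrium <- function(ge, gi, params) {
  ge <- ge * params$gbar_e; gi <- gi * params$gbar_i; gl <- params$gbar_l
  (ge * params$E_e + gi * params$E_i + gl * params$E_l) / (ge + gi + gl)
}

#' Pooled FFFB inhibitory conductance
#'
#' `gi = Gi * (ff + fb)` with `ff = ff_gain * [mean(net input) - ff_floor]+`
#' and `fb = fb_gain * mean(activity)` (the caller is responsible for the
#' feedback time average, see [settle()]). Zero for a silent, unstimulated
#' layer and nondecreasing in both arguments.
#'
#' @param layer_net_input numeric vector of per-unit net excitatory input.
#' @param layer_activity numeric vector of per-unit activations.
#' @param params an [inhib_params()].
#' @return scalar pooled inhibitory conductance.
#' @export
fffb_inhibition <- function(layer_net_input, layer_activity, params) {
  stopifnot(all(layer_net_input >= 0), all(layer_activity >= 0))
  ff <- params$ff_gain * max(0, mean(layer_net_input) - params$ff_floor)
  fb <- params$fb_gain * mean(layer_activity)
  params$Gi * (ff + fb)
}

#' Settle a layer to its activity fixed point
#'
#' Iterates net input -> FFFB inhibition -> membrane update -> activation for
#' a single layer receiving clamped external projections, until the maximum
#' activity change falls below `tol` or the cycle budget is exhausted. The
#' feedback inhibition term is exponentially averaged (`fb_tau`) and the
#' activations are partially stepped each cycle, which keeps small layers
#' from oscillating.
#'
#' @param sender_activities list of clamped sender activity vectors.
#' @param projections list of [projection()]s matching `sender_activities`.
#' @param unit a [unit_params()].
#' @param inhib an [inhib_params()].
#' @param n_cycles maximum number of settling cycles (default 50).
#' @param tol convergence tolerance on the per-cycle activity change.
#' @param dt Euler step for the membrane update.
#' @param total_rel optional static normalizer passed to [net_excitation()].
#' @return list with `y` (settled activations), `ge`, `gi`, `vm`,
#'   `cycles` used, and a `converged` flag.
#' @export
settle <- function(sender_activities, projections, unit = unit_params(),
                   inhib = inhib_params(), n_cycles = 50, tol = 1e-4,
                   dt = 0.3, total_rel = NULL) {
  stopifnot(n_cycles >= 1)
  ge <- net_excitation(sender_activities, projections, total_rel = total_rel)
  n <- length(ge)
  y <- numeric(n)
  vm <- rep(unit$E_l, n)
  fb_avg <- 0
  y_tau <- 0.5
  converged <- FALSE
  cyc <- 0L
  for (cyc in seq_len(n_cycles)) {
    fb_avg <- fb_avg + inhib$fb_tau * (mean(y) - fb_avg)
    ff <- inhib$ff_gain * max(0, mean(ge) - inhib$ff_floor)
    gi <- inhib$Gi * (ff + inhib$fb_gain * fb_avg)
    vm <- step_membrane(vm, ge, gi, unit, dt = dt)
    y_new <- y + y_tau * (unit_activation(ge, gi, unit) - y)
    if (any(!is.finite(y_new)))
      stop("settle: non-finite activity in layer of size ", n)
    delta <- max(abs(y_new - y))
    y <- y_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(y = y, ge = ge, gi = gi, vm = vm, cycles = cyc, converged = converged)
}
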