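#' Tunable parameters of the PBWM circuit
#'
#' Collects every constant of the stripe-structured circuit and its learning
#' rules. Defaults are the operating point used for all shipped analyses.
#'
#' @param bump_width circular-Gaussian sigma (radians) of color bumps.
#' @param n_units units per ring layer.
#' @param chunk a [chunk_spec()] for the chunk layer (chunk models only).
#' @param out_unit,out_inhib neuron and pooled-inhibition parameters of the
#'   response layer.
#' @param out_cycles settling cycle budget for the response layer.
#' @param out_floor drive peak below which the response layer is treated as
#'   silent (no settling).
#' @param target_amp amplitude of the clamped target bump during the outcome
#'   phase of supervised learning; matched to the attainable settled activity
#'   so the error-driven rule has a reachable fixed point.
#' @param w_decay slow multiplicative decay of the plastic response mappings
#'   per training event (homeostatic depression): prevents mismatched
#'   content/target pairs, which occur whenever the wrong stripe is read
#'   out, from uniformly saturating the mapping.
#' @param noise_sd SD of Gaussian exploration noise added to each striatal
#'   Go-NoGo drive.
#' @param gate_compete pallidal competition strength in `[0, 1]` applied to
#'   *output* gating: each stripe's noisy drive is reduced by this fraction
#'   of the strongest positive drive among the other stripes before
#'   thresholding, so read-out tends to select a single maintained
#'   representation while still permitting parallel read-out when drives are
#'   comparable. Input gating is uncompeted: stripes load independently, and
#'   the same stimulus may be stored in several stripes at once.
#' @param tag_decay per-trial multiplicative decay of eligibility tags.
#' @param gate_decay slow multiplicative decay of all Go/NoGo weights per
#'   reward event (passive forgetting); keeps rarely used gating routes
#'   recoverable by exploration instead of absorbing at a saturated NoGo
#'   state.
#' @param suppress_scale weight of the suppression (no-fire) eligibility
#'   tags relative to the fire tags in the opponent update. At 0 the rule is
#'   the pure gating-event scheme (withholding never learns), which lets
#'   whole networks absorb into permanent non-response; at 1 withholding is
#'   credited as strongly as acting and networks almost never withhold. The
#'   default 0.25 keeps gating recoverable while preserving the "giving up"
#'   regime (non-responses under sparse reward) the circuit is known for.
#' @param alpha_v critic (expected reward) learning rate.
#' @param lrate_go,lrate_nogo striatal learning rates.
#' @param lrate_out learning rate of the plastic response mappings.
#' @param burst_gain,dip_gain dopamine gains on positive / negative reward
#'   prediction errors.
#' @param reward_span closeness threshold in degrees: reward is
#'   `1 - |error|/reward_span`, positive below the span, negative beyond it.
#' @param resultant_floor population-vector resultant length below which the
#'   response layer is non-decodable (counts as a non-response).
#' @param v_init initial critic value; `NA` (default) initializes at the
#'   expected reward of a uniform random reporter (`1 - 90/reward_span`), so
#'   early dopamine signals reflect deviations from chance rather than a
#'   transient flood of dips while the critic finds the baseline.
#' @param w_init_gate upper bound of the uniform initialization of Go/NoGo
#'   weights.
#' @param w_init_out upper bound of the uniform initialization of the plastic
#'   response mappings.
#' @return list of class `pbwm_params`.
#' @export
pbwm_params <- function(bump_width = 0.72, n_units = 20,
                        chunk = NULL,
                        out_unit = unit_params(), out_inhib = inhib_params(),
                        out_cycles = 30, out_floor = 0.005,
                        target_amp = 0.85, w_decay = 0.002,
                        noise_sd = 0.2, gate_compete = 0.6,
                        tag_decay = 0.9, gate_decay = 3e-4,
                        suppress_scale = 0.25,
                        alpha_v = 0.05, lrate_go = 0.02, lrate_nogo = 0.02,
                        lrate_out = 0.05,
                        burst_gain = 1, dip_gain = 1,
                        reward_span = 45, resultant_floor = 0.05,
                        v_init = NA_real_,
                        w_init_gate = 0.1, w_init_out = 0.3) {
  structure(list(bump_width = bump_width, n_units = n_units, chunk = chunk,
                 out_unit = out_unit, out_inhib = out_inhib,
                 out_cycles = out_cycles, out_floor = out_floor,
                 target_amp = target_amp, w_decay = w_decay,
                 noise_sd = noise_sd, gate_compete = gate_compete,
                 tag_decay = tag_decay,
                 gate_decay = gate_decay, suppress_scale = suppress_scale,
                 alpha_v = alpha_v, lrate_go = lrate_go,
                 lrate_nogo = lrate_nogo, lrate_out = lrate_out,
                 burst_gain = burst_gain, dip_gain = dip_gain,
                 reward_span = reward_span, resultant_floor = resultant_floor,
                 v_init = v_init,
                 w_init_gate = w_init_gate, w_init_out = w_init_out),
            class = "pbwm_params")
}

#' Construct a PBWM network
#'
#' Builds the stripe-structured circuit: per-stripe PFC maintenance state, a
#' striatal Go/NoGo module per stripe and gating type (input and output), the
#' plastic direct input-to-output mapping, and per-stripe plastic
#' PFC-output-to-output mappings. In a chunk model the last stripe's
#' superficial layer is fed by the chunk layer; all other stripes are fed by
#' the raw sensory input. Weight matrices are initialized from the current
#' RNG state, so seed before calling for reproducible networks.
#'
#' @param model `"chunk"` or `"no_chunk"`.
#' @param n_stripes number of PFC stripes (chunk models need at least 2).
#' @param n_orient number of discrete orientations (default 4).
#' @param params a [pbwm_params()].
#' @return object of class `pbwm_network`.
#' @export
pbwm_network <- function(model = c("chunk", "no_chunk"), n_stripes = 2,
                         n_orient = 4, params = pbwm_params()) {
  model <- match.arg(model)
  if (model == "chunk" && n_stripes < 2)
    stop("a chunk model needs at least 2 stripes (one input-fed, one chunk-fed)")
  if (n_stripes < 1) stop("need at least one stripe")
  source <- if (model == "chunk") {
    c(rep("input", n_stripes - 1), "chunk")
  } else {
    rep("input", n_stripes)
  }
  if (model == "chunk" && is.null(params$chunk))
    params$chunk <- chunk_spec(n_pfc = n_stripes, n_units = params$n_units)
  nu <- params$n_units
  n_control <- n_orient + 2 + n_stripes  # orientation one-hot, store/recall bits, occupancy
  rw <- function(nr, nc, hi) matrix(stats::runif(nr * nc, 0, hi), nr, nc)
  net <- list(
    model = model, n_stripes = n_stripes, n_orient = n_orient,
    n_units = nu, n_control = n_control,
    stripe_source = source,
    go_in = rw(n_control, n_stripes, params$w_init_gate),
    nogo_in = rw(n_control, n_stripes, params$w_init_gate),
    go_out = rw(n_control, n_stripes, params$w_init_gate),
    nogo_out = rw(n_control, n_stripes, params$w_init_gate),
    tags_in = matrix(0, n_control, n_stripes),
    tags_out = matrix(0, n_control, n_stripes),
    tags_in_s = matrix(0, n_control, n_stripes),
    tags_out_s = matrix(0, n_control, n_stripes),
    w_direct = rw(nu, nu, params$w_init_out),
    w_pfc_out = lapply(seq_len(n_stripes), function(i) rw(nu, nu, params$w_init_out)),
    deep = matrix(0, nu, n_stripes),
    maintained = rep(FALSE, n_stripes),
    V = if (is.na(params$v_init)) 1 - 90 / params$reward_span else params$v_init,
    params = params
  )
  class(net) <- "pbwm_network"
  net
}

#' @export
print.pbwm_network <- function(x, ...) {
  cat(sprintf("PBWM network: %s model, %d stripes (%s), %d-unit rings, %d orientations\n",
              x$model, x$n_stripes, paste(x$stripe_source, collapse = "/"),
              x$n_units, x$n_orient))
  cat(sprintf("  maintained stripes: %d; critic V = %.3f\n",
              sum(x$maintained), x$V))
  invisible(x)
}

#' Control-input vector for the striatal modules
#'
#' Concatenates the one-hot orientation, a store bit, a recall bit, and the
#' per-stripe occupancy summary. This is the presynaptic activity pattern
#' seen by every Go/NoGo unit.
#'
#' @param net a [pbwm_network()].
#' @param orientation integer orientation id in `1:n_orient`, or `NA` for
#'   none.
#' @param phase `"store"` or `"recall"`.
#' @return numeric vector of length `net$n_control`.
#' @export
control_vector <- function(net, orientation, phase = c("store", "recall")) {
  phase <- match.arg(phase)
  ori <- numeric(net$n_orient)
  if (!is.na(orientation)) {
    stopifnot(orientation >= 1, orientation <= net$n_orient)
    ori[orientation] <- 1
  }
  c(ori, as.numeric(phase == "store"), as.numeric(phase == "recall"),
    as.numeric(net$maintained))
}

# noisy Go - NoGo drive for one gating type; output gating additionally
# passes through pallidal competition
gate_drives <- function(net, control, go, nogo, compete = 0) {
  drive <- as.vector(crossprod(go, control) - crossprod(nogo, control))
  drive <- drive + stats::rnorm(net$n_stripes, 0, net$params$noise_sd)
  compete_drives(drive, compete)
}

#' Pallidal competition between stripe gating drives
#'
#' Subtracts from each stripe's drive a fraction of the strongest positive
#' drive among the *other* stripes. With `compete = 0` stripes are fully
#' independent; with `compete = 1` at most the strongest positive drive can
#' survive. Intermediate values bias gating toward a single winner while
#' still allowing parallel gating when drives are comparable.
#'
#' @param drives numeric vector of per-stripe noisy Go-NoGo drives.
#' @param compete competition strength in `[0, 1]`.
#' @return adjusted drives (same length).
#' @export
compete_drives <- function(drives, compete = 0.6) {
  stopifnot(compete >= 0, compete <= 1)
  n <- length(drives)
  if (n == 1 || compete == 0) return(drives)
  dp <- pmax(drives, 0)
  i1 <- which.max(dp)
  rival <- rep(dp[i1], n)
  rival[i1] <- max(dp[-i1])
  drives - compete * rival
}

#' Input gating: load superficial content into maintenance
#'
#' Each stripe's striatal module computes a noisy Go-minus-NoGo drive from
#' the control inputs; the gate fires when the drive is positive. A firing
#' stripe replaces its maintained (deep) content with its current superficial
#' content (overwriting whatever was there); non-firing stripes keep their
#' prior content untouched. Eligibility tags are stamped with the control
#' activity for every fired gate; non-firing stripes stamp complementary
#' suppression tags, so that a later dopamine signal can also credit or
#' punish the decision *not* to gate (opponent credit assignment over the
#' fire/no-fire choice).
#'
#' @param net a [pbwm_network()].
#' @param control control-input vector from [control_vector()].
#' @param superficial `n_units x n_stripes` matrix of settled superficial
#'   activity (each stripe's candidate content).
#' @return list with the updated `net` and a `decisions` data.frame
#'   (stripe, fired, drive).
#' @export
input_gate <- function(net, control, superficial) {
  stopifnot(ncol(superficial) == net$n_stripes,
            nrow(superficial) == net$n_units)
  drives <- gate_drives(net, control, net$go_in, net$nogo_in)
  fired <- drives > 0
  for (j in seq_len(net$n_stripes)) {
    if (fired[j]) {
      net$deep[, j] <- superficial[, j]
      net$maintained[j] <- TRUE
      net$tags_in[, j] <- net$tags_in[, j] + control
    } else {
      net$tags_in_s[, j] <- net$tags_in_s[, j] + control
    }
  }
  list(net = net,
       decisions = data.frame(stripe = seq_len(net$n_stripes),
                              gate_type = "input",
                              fired = fired, drive = drives))
}

#' Maintenance across trial boundaries
#'
#' Deep-layer content persists unchanged (no drift, no decay) until the
#' stripe is input-gated again or cleared; superficial layers are transient
#' and recomputed each trial. Provided for contract clarity; maintenance is
#' literally the identity on the deep state.
#'
#' @param net a [pbwm_network()].
#' @return `net`, unchanged.
#' @export
maintain <- function(net) net

#' Clear all maintained content
#' @param net a [pbwm_network()].
#' @return `net` with empty stripes.
#' @export
clear_maintenance <- function(net) {
  net$deep[] <- 0
  net$maintained[] <- FALSE
  net
}

#' Output gating: read maintained content out to the response pathway
#'
#' Each stripe's output-gate module fires on a positive noisy Go-minus-NoGo
#' drive. Fired stripes copy their maintained content to their output layer;
#' the response layer then receives the scale-weighted average of all gated
#' output bumps through the per-stripe plastic mappings. If no stripe fires
#' (or only empty stripes fire) the trial is a non-response candidate.
#'
#' @param net a [pbwm_network()].
#' @param control control-input vector for the recall phase.
#' @return list with updated `net` (tags stamped), `decisions` data.frame,
#'   `out_deep` (`n_units x n_stripes`, zero for non-gated stripes), and
#'   `n_fired`.
#' @export
output_gate <- function(net, control) {
  drives <- gate_drives(net, control, net$go_out, net$nogo_out,
                        compete = net$params$gate_compete)
  fired <- drives > 0
  out_deep <- matrix(0, net$n_units, net$n_stripes)
  for (j in seq_len(net$n_stripes)) {
    if (fired[j]) {
      out_deep[, j] <- net$deep[, j]
      net$tags_out[, j] <- net$tags_out[, j] + control
    } else {
      net$tags_out_s[, j] <- net$tags_out_s[, j] + control
    }
  }
  list(net = net,
       decisions = data.frame(stripe = seq_len(net$n_stripes),
                              gate_type = "output",
                              fired = fired, drive = drives),
       out_deep = out_deep, n_fired = sum(fired))
}

#' Number of stripes output-gated on a recall trial
#' @param decisions the `decisions` data.frame from [output_gate()].
#' @return integer count of fired output gates.
#' @export
count_output_gated <- function(decisions) {
  sum(decisions$fired[decisions$gate_type == "output"])
}

#' Settle the response layer from gated output content
#'
#' Drives the response ring through the per-stripe plastic mappings of the
#' stripes whose output gates fired, as a scale-weighted average, and settles
#' with FFFB inhibition.
#'
#' @param net a [pbwm_network()].
#' @param out_deep `n_units x n_stripes` gated output content.
#' @param fired logical vector of fired output gates.
#' @return list: settled `y`, decode result `dec`.
#' @export
response_from_stripes <- function(net, out_deep, fired) {
  p <- net$params
  nu <- net$n_units
  idx <- which(fired)
  if (length(idx) == 0) {
    return(list(y = numeric(nu),
                dec = list(theta = NA_real_, resultant = 0, decodable = FALSE)))
  }
  ge <- numeric(nu)
  for (j in idx) {
    ge <- ge + as.vector(crossprod(net$w_pfc_out[[j]], out_deep[, j])) / nu
  }
  ge <- ge / length(idx)
  res <- response_settle(ge, p)
  list(y = res$y, dec = decode_color(res$y, floor = p$resultant_floor))
}

# settle the response ring from a raw readout drive (silent below the floor)
response_settle <- function(ge, p) {
  if (max(ge) < p$out_floor) {
    return(list(y = numeric(length(ge)), ge = ge, gi = 0, cycles = 0L,
                converged = TRUE))
  }
  spec <- list(unit = p$out_unit, inhib = p$out_inhib, n_cycles = p$out_cycles)
  settle_ge(ge, spec)
}
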