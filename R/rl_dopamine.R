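#' Reward for a continuous-report response
#'
#' Reward falls linearly with the absolute circular error:
#' `reward = 1 - |error| / reward_span`. It is maximal (+1) at zero error,
#' zero exactly at the closeness threshold (`reward_span` degrees, default
#' 45), and negative beyond it (down to `1 - 180/span` at the antipode), so
#' responses that are not sufficiently close are punished. Non-responses are
#' scored upstream by substituting a uniform random report (see
#' [score_recall()]).
#'
#' @param reported reported color in radians.
#' @param target target color in radians.
#' @param reward_span closeness threshold in degrees.
#' @return scalar reward.
#' @export
compute_reward <- function(reported, target, reward_span = 45) {
  err <- abs(circular_error(reported, target))
  1 - err / reward_span
}

#' Rescorla-Wagner critic update
#'
#' Delta rule on the expected reward: `delta = reward - V`,
#' `V <- V + alpha_v * delta`. Under stationary rewards V converges
#' geometrically to the mean reward.
#'
#' @param reward received reward.
#' @param V current expected reward.
#' @param alpha_v critic learning rate.
#' @return list with `delta` (the reward prediction error) and updated `V`.
#' @export
rpe <- function(reward, V, alpha_v = 0.05) {
  delta <- reward - V
  list(delta = delta, V = V + alpha_v * delta)
}

#' Dopamine burst/dip scaling of a reward prediction error
#'
#' Positive RPEs (bursts) are scaled by `burst_gain`, negative RPEs (dips)
#' by `dip_gain`; their balance controls how strongly reward versus
#' punishment shapes the gating policy.
#'
#' @param delta reward prediction error.
#' @param burst_gain multiplier on positive RPEs (`>= 0`).
#' @param dip_gain multiplier on negative RPEs (`>= 0`).
#' @return effective (scaled) RPE.
#' @export
da_modulate <- function(delta, burst_gain = 1, dip_gain = 1) {
  stopifnot(burst_gain >= 0, dip_gain >= 0)
  ifelse(delta > 0, burst_gain * delta, dip_gain * delta)
}

#' Dopamine-modulated striatal plasticity
#'
#' Applies the three-factor rule to a Go/NoGo weight pair using the
#' eligibility tags stamped at recent gating events:
#' `go <- go + lrate_go * eff_delta * tag` and
#' `nogo <- nogo - lrate_nogo * eff_delta * tag`, both clipped to `[0, 1]`.
#' A positive effective RPE therefore reinforces the Go pathway of recently
#' used gates and weakens their NoGo opposition; a negative RPE does the
#' reverse, strengthening NoGo suppression of the strategy that failed.
#' Untagged synapses are untouched.
#'
#' @param go,nogo weight matrices (control inputs x stripes).
#' @param tags eligibility-tag matrix of the same shape, `>= 0`.
#' @param eff_delta effective (dopamine-scaled) RPE.
#' @param lrate_go,lrate_nogo learning rates.
#' @return list with updated `go` and `nogo`.
#' @export
update_striatal <- function(go, nogo, tags, eff_delta,
                            lrate_go = 0.02, lrate_nogo = 0.02) {
  stopifnot(all(tags >= 0))
  go <- pmin(pmax(go + lrate_go * eff_delta * tags, 0), 1)
  nogo <- pmin(pmax(nogo - lrate_nogo * eff_delta * tags, 0), 1)
  list(go = go, nogo = nogo)
}

#' Decay eligibility tags by one trial
#' @param tags tag matrix.
#' @param decay multiplicative per-trial decay in `[0, 1]`.
#' @return decayed tags.
#' @export
decay_tags <- function(tags, decay = 0.9) tags * decay

#' Gating-policy metric: rectified normalized Go-NoGo contrast
#'
#' For each stripe, sums the Go and NoGo weights over the control-input rows
#' that represent the store orientations and returns
#' `alpha_j = [ (sum Go - sum NoGo) / (sum Go + sum NoGo) ]+`, the rectified
#' normalized contrast in `[0, 1]`. When Go does not exceed NoGo the net
#' thalamic drive is zero and so is alpha. A zero denominator yields 0.
#'
#' @param go,nogo weight matrices (control inputs x stripes).
#' @param orientation_rows integer indices of the orientation block of the
#'   control inputs.
#' @return numeric vector `alpha_j`, one value per stripe.
#' @export
gating_policy_metric <- function(go, nogo, orientation_rows) {
  sg <- colSums(go[orientation_rows, , drop = FALSE])
  sn <- colSums(nogo[orientation_rows, , drop = FALSE])
  tot <- sg + sn
  alpha <- ifelse(tot > 0, (sg - sn) / tot, 0)
  pmax(0, alpha)
}
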