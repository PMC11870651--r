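#' Settle the response layer through the direct input-to-output mapping
#'
#' @param net a [pbwm_network()].
#' @param sensory sensory bump.
#' @return list: settled `y`, decode result `dec`.
#' @export
response_from_input <- function(net, sensory) {
  p <- net$params
  ge <- as.vector(crossprod(net$w_direct, sensory)) / net$n_units
  res <- response_settle(ge, p)
  list(y = res$y, dec = decode_color(res$y, floor = p$resultant_floor))
}

#' Error-driven update of a plastic response mapping
#'
#' Two-phase contrastive rule: the response layer first settles under the
#' current weights (expectation phase, activity `y`); the target color bump
#' is then clamped (outcome phase) and each synapse moves by the product of
#' its presynaptic activity and the outcome-minus-expectation difference:
#' `w[i, j] <- (1 - decay) * w[i, j] + lrate * x[i] * (t[j] - y[j])`, clipped
#' to `[0, 1]`. At zero output error and zero decay nothing changes; repeated
#' training drives the settled output toward the target bump. The slow decay
#' acts as homeostatic depression: occasional mismatched content/target pairs
#' push weights up diffusely, and without an opposing force they would
#' saturate the mapping toward a flat (undecodable) state.
#'
#' @param w weight matrix (senders x output units).
#' @param pre presynaptic activity vector.
#' @param y settled output activity (expectation phase).
#' @param target_bump clamped target activity (outcome phase).
#' @param lrate learning rate.
#' @param decay multiplicative weight decay per training event.
#' @return updated weight matrix.
#' @export
train_step_output <- function(w, pre, y, target_bump, lrate = 0.05,
                              decay = 0) {
  stopifnot(length(pre) == nrow(w), length(y) == ncol(w),
            length(target_bump) == ncol(w))
  pmin(pmax((1 - decay) * w + lrate * outer(pre, target_bump - y), 0), 1)
}
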