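#' Configuration of a training run
#'
#' Bundles the task, architecture, and learning constants for one simulated
#' network. The shipped default regimen is 500 epochs of 100 trials (store
#' and recall events both count toward the trial budget); analyses in this
#' package's tests use reduced regimens that are stated where they are run.
#'
#' @param model `"chunk"` or `"no_chunk"`.
#' @param n_stripes number of PFC stripes.
#' @param set_size items per episode (2-4).
#' @param n_orient number of discrete orientations; defaults to the set
#'   size, so the probe inventory matches the binding problem the condition
#'   poses.
#' @param epochs training epochs.
#' @param trials_per_epoch store+recall events per epoch; episodes of
#'   `set_size + 1` trials are packed to fill it.
#' @param eval_episodes episodes of the frozen-weights evaluation phase.
#' @param burst_gain,dip_gain dopamine gains (override the same fields of
#'   `params`).
#' @param noise_sd striatal exploration noise SD (overrides `params`).
#' @param params a [pbwm_params()] carrying every remaining constant.
#' @return list of class `run_config`.
#' @export
run_config <- function(model = c("chunk", "no_chunk"), n_stripes = 2,
                       set_size = 2, n_orient = set_size,
                       epochs = 500, trials_per_epoch = 100,
                       eval_episodes = 100,
                       burst_gain = NULL, dip_gain = NULL, noise_sd = NULL,
                       params = pbwm_params()) {
  model <- match.arg(model)
  if (model == "chunk" && n_stripes < 2)
    stop("chunk model needs at least 2 stripes")
  if (set_size < 2 || set_size > n_orient)
    stop("set_size must be between 2 and n_orient (", n_orient, ")")
  stopifnot(epochs >= 1, trials_per_epoch >= set_size + 1)
  if (!is.null(burst_gain)) params$burst_gain <- burst_gain
  if (!is.null(dip_gain)) params$dip_gain <- dip_gain
  if (!is.null(noise_sd)) params$noise_sd <- noise_sd
  structure(list(model = model, n_stripes = n_stripes, set_size = set_size,
                 n_orient = n_orient, epochs = epochs,
                 trials_per_epoch = trials_per_epoch,
                 eval_episodes = eval_episodes, params = params),
            class = "run_config")
}

# Pre-generate every random quantity one block of episodes consumes: task
# variables (orientations, colors, probe), striatal exploration noise, and
# the uniform report substituted for non-responses. Keeping all RNG use in R
# makes runs reproducible from the seed alone and lets the compiled engine
# be compared against the R reference implementation on identical inputs.
gen_task_inputs <- function(config, K, n_stripes) {
  n_store <- config$set_size
  orient <- matrix(0L, K, n_store)
  for (k in seq_len(K)) orient[k, ] <- sample.int(config$n_orient, n_store)
  colors <- matrix(stats::runif(K * n_store, 0, 2 * pi), K, n_store)
  probe <- sample.int(n_store, K, replace = TRUE)
  noise <- matrix(stats::rnorm(K * (n_store + 1) * n_stripes, 0,
                               config$params$noise_sd),
                  K, (n_store + 1) * n_stripes)
  guess <- stats::runif(K, 0, 2 * pi)
  list(orient = orient, colors = colors, probe = probe, noise = noise,
       guess = guess)
}

# constants handed to the compiled episode engine
engine_cfg <- function(net, config) {
  p <- net$params
  settle_consts <- function(unit, inhib, cycles) {
    c(unit$gbar_e, unit$gamma,
      unit$gbar_i * (unit$E_i - unit$Theta) / (unit$Theta - unit$E_e),
      unit$gbar_l * (unit$E_l - unit$Theta) / (unit$Theta - unit$E_e),
      inhib$Gi, inhib$ff_gain, inhib$ff_floor, inhib$fb_gain, inhib$fb_tau,
      cycles)
  }
  chunk_stripe <- which(net$stripe_source == "chunk")
  cs <- p$chunk
  if (is.null(cs)) cs <- chunk_spec(n_pfc = net$n_stripes, n_units = net$n_units)
  list(ns = net$n_stripes, nu = net$n_units, n_store = config$set_size,
       n_orient = net$n_orient,
       chunk_stripe = if (length(chunk_stripe)) chunk_stripe[1] - 1L else -1L,
       bump_width = p$bump_width, tag_decay = p$tag_decay,
       gate_decay = p$gate_decay, suppress_scale = p$suppress_scale,
       lrate_go = p$lrate_go, lrate_nogo = p$lrate_nogo,
       lrate_out = p$lrate_out, w_decay = p$w_decay,
       target_amp = p$target_amp, alpha_v = p$alpha_v,
       burst_gain = p$burst_gain, dip_gain = p$dip_gain,
       reward_span = p$reward_span, resultant_floor = p$resultant_floor,
       out_floor = p$out_floor, gate_compete = p$gate_compete,
       chunk_settle = settle_consts(cs$unit, cs$inhib, cs$n_cycles),
       out_settle = settle_consts(p$out_unit, p$out_inhib, p$out_cycles),
       chunk_kernel = cs$kernel, chunk_in_scale = cs$input_scale,
       chunk_pfc_scale = cs$pfc_scale,
       chunk_total_rel = cs$input_scale + cs$pfc_scale * cs$n_pfc)
}

run_episode_block <- function(net, config, K, learn = TRUE) {
  task <- gen_task_inputs(config, K, net$n_stripes)
  out <- .run_episodes_core(net, engine_cfg(net, config), task, learn)
  for (f in c("go_in", "nogo_in", "go_out", "nogo_out", "w_direct",
              "w_pfc_out", "V")) {
    net[[f]] <- out[[f]]
  }
  colnames(out$records) <- c("error_deg", "reward", "delta", "non_response",
                             "n_out_gated", "lag", "ocv",
                             paste0("occ.", seq_len(net$n_stripes)))
  list(net = net, records = out$records)
}

# Reference implementation of one episode in plain R over the public
# operations, consuming the same pre-generated inputs as the compiled
# engine; used by the equivalence tests and kept deliberately simple.
run_episode_ref <- function(net, config, task, k, learn = TRUE) {
  p <- net$params
  nu <- net$n_units
  ns <- net$n_stripes
  net$deep[] <- 0
  net$maintained[] <- FALSE
  net$tags_in[] <- 0; net$tags_out[] <- 0
  net$tags_in_s[] <- 0; net$tags_out_s[] <- 0
  n_store <- config$set_size
  chunk_stripe <- which(net$stripe_source == "chunk")
  for (t in seq_len(n_store)) {
    theta <- task$colors[k, t]
    sensory <- encode_color(theta, p$bump_width, nu)
    superficial <- matrix(sensory, nu, ns)
    if (length(chunk_stripe)) {
      pfc <- lapply(which(net$maintained), function(j) net$deep[, j])
      cs <- chunk_settle(sensory, pfc, p$chunk)
      dec <- decode_color(cs$y)
      m_theta <- if (dec$decodable) dec$theta else theta
      superficial[, chunk_stripe] <- encode_color(m_theta, p$bump_width, nu)
    }
    control <- control_vector(net, task$orient[k, t], "store")
    drives <- as.vector(crossprod(net$go_in, control) -
                          crossprod(net$nogo_in, control)) +
      task$noise[k, (t - 1) * ns + seq_len(ns)]
    fired <- drives > 0
    for (j in seq_len(ns)) {
      if (fired[j]) {
        net$deep[, j] <- superficial[, j]
        net$maintained[j] <- TRUE
        net$tags_in[, j] <- net$tags_in[, j] + control
      } else {
        net$tags_in_s[, j] <- net$tags_in_s[, j] + control
      }
    }
    if (learn) {
      r <- response_from_input(net, sensory)
      net$w_direct <- train_step_output(net$w_direct, sensory, r$y,
                                        p$target_amp * sensory, p$lrate_out,
                                        p$w_decay)
    }
    net$tags_in <- net$tags_in * p$tag_decay
    net$tags_out <- net$tags_out * p$tag_decay
    net$tags_in_s <- net$tags_in_s * p$tag_decay
    net$tags_out_s <- net$tags_out_s * p$tag_decay
  }
  occupied <- net$maintained
  probe <- task$probe[k]
  target <- task$colors[k, probe]
  control <- control_vector(net, task$orient[k, probe], "recall")
  drives <- as.vector(crossprod(net$go_out, control) -
                        crossprod(net$nogo_out, control)) +
    task$noise[k, n_store * ns + seq_len(ns)]
  drives <- compete_drives(drives, p$gate_compete)
  fired <- drives > 0
  n_fired <- sum(fired)
  out_deep <- matrix(0, nu, ns)
  for (j in seq_len(ns)) {
    if (fired[j]) {
      out_deep[, j] <- net$deep[, j]
      net$tags_out[, j] <- net$tags_out[, j] + control
    } else {
      net$tags_out_s[, j] <- net$tags_out_s[, j] + control
    }
  }
  resp <- response_from_stripes(net, out_deep, fired)
  non_resp <- n_fired == 0L || !resp$dec$decodable
  eff_report <- if (non_resp) task$guess[k] else resp$dec$theta
  err <- circular_error(eff_report, target)
  reward <- 1 - abs(err) / p$reward_span
  delta <- reward - net$V
  net$V <- net$V + p$alpha_v * delta
  eff <- if (delta > 0) p$burst_gain * delta else p$dip_gain * delta
  if (learn) {
    t_in <- net$tags_in - p$suppress_scale * net$tags_in_s
    t_out <- net$tags_out - p$suppress_scale * net$tags_out_s
    gd <- 1 - p$gate_decay
    net$go_in <- pmin(pmax(gd * net$go_in + p$lrate_go * eff * t_in, 0), 1)
    net$nogo_in <- pmin(pmax(gd * net$nogo_in - p$lrate_nogo * eff * t_in, 0), 1)
    net$go_out <- pmin(pmax(gd * net$go_out + p$lrate_go * eff * t_out, 0), 1)
    net$nogo_out <- pmin(pmax(gd * net$nogo_out - p$lrate_nogo * eff * t_out, 0), 1)
    tb <- p$target_amp * encode_color(target, p$bump_width, nu)
    for (j in which(fired & net$maintained)) {
      net$w_pfc_out[[j]] <- train_step_output(net$w_pfc_out[[j]],
                                              net$deep[, j], resp$y, tb,
                                              p$lrate_out, p$w_decay)
    }
  }
  list(net = net,
       recall = list(error_deg = err, reward = reward, delta = delta,
                     non_response = non_resp, n_out_gated = n_fired,
                     lag = n_store + 1L - probe,
                     ocv = ocv(task$colors[k, seq_len(n_store)], probe),
                     occupied = occupied))
}

#' Train a PBWM network on the color-wheel task
#'
#' Runs the full loop for every trial: settle the superficial (and, in chunk
#' models, chunk) layers, take the striatal input-gating decisions, train the
#' direct report pathway, and at each recall probe take output-gating
#' decisions, settle the response, deliver the reward, convert it to a
#' dopamine-scaled reward prediction error, and apply tag-based Go/NoGo
#' plasticity. Deterministic given `seed`.
#'
#' @param config a [run_config()].
#' @param seed integer seed for all randomness of the run.
#' @return object of class `pbwm_fit`: the trained `net`, the `config` and
#'   `seed`, and `epoch_log`, a data.frame with per-epoch mean absolute
#'   recall error, non-response rate, mean reward, and the input-gating
#'   policy metric `alpha` per stripe.
#' @export
train_network <- function(config, seed) {
  stopifnot(inherits(config, "run_config"))
  set.seed(seed)
  net <- pbwm_network(config$model, config$n_stripes, config$n_orient,
                      config$params)
  ori_rows <- seq_len(config$n_orient)
  n_ep <- max(1L, round(config$trials_per_epoch / (config$set_size + 1)))
  ne <- config$epochs
  log_err <- numeric(ne); log_nr <- numeric(ne); log_rw <- numeric(ne)
  log_alpha <- matrix(0, ne, config$n_stripes)
  for (epoch in seq_len(ne)) {
    out <- run_episode_block(net, config, n_ep, learn = TRUE)
    net <- out$net
    if (!is.finite(net$V)) stop("train_network: critic diverged at epoch ", epoch)
    rec <- out$records
    log_err[epoch] <- mean(abs(rec[, "error_deg"]))
    log_nr[epoch] <- mean(rec[, "non_response"])
    log_rw[epoch] <- mean(rec[, "reward"])
    log_alpha[epoch, ] <- gating_policy_metric(net$go_in, net$nogo_in, ori_rows)
  }
  epoch_log <- data.frame(epoch = seq_len(ne), mean_abs_err = log_err,
                          nonresp_rate = log_nr, mean_reward = log_rw)
  colnames(log_alpha) <- paste0("alpha.", seq_len(config$n_stripes))
  epoch_log <- cbind(epoch_log, as.data.frame(log_alpha))
  structure(list(net = net, config = config, seed = seed,
                 epoch_log = epoch_log),
            class = "pbwm_fit")
}

#' @export
print.pbwm_fit <- function(x, ...) {
  n <- nrow(x$epoch_log)
  cat(sprintf("pbwm_fit: %s model, %d stripes, set size %d, %d epochs (seed %d)\n",
              x$config$model, x$config$n_stripes, x$config$set_size, n, x$seed))
  cat(sprintf("  final mean |error| %.1f deg, non-response rate %.2f\n",
              x$epoch_log$mean_abs_err[n], x$epoch_log$nonresp_rate[n]))
  invisible(x)
}

#' Evaluate a trained network with frozen weights
#'
#' Runs episodes through the trained network with all plasticity switched
#' off (gating noise stays on: the learned policy is stochastic) and records
#' one row per recall probe.
#'
#' @param fit a `pbwm_fit` from [train_network()].
#' @param n_episodes number of evaluation episodes.
#' @param seed seed for the evaluation phase.
#' @return data.frame with columns `error_deg`, `abs_err`, `reward`,
#'   `non_response`, `n_out_gated`, `lag`, `ocv`, `max_load`, `n_occupied`,
#'   `all_occupied`, and per-stripe occupancy flags `occ.1 ...` measured on
#'   the episode's final (maximal-load) store trial.
#' @export
evaluate_network <- function(fit, n_episodes = 100, seed = 1) {
  stopifnot(inherits(fit, "pbwm_fit"))
  set.seed(seed)
  out <- run_episode_block(fit$net, fit$config, n_episodes, learn = FALSE)
  rec <- as.data.frame(out$records)
  occ <- rec[, grep("^occ\\.", names(rec)), drop = FALSE]
  data.frame(episode = seq_len(n_episodes),
             error_deg = rec$error_deg,
             abs_err = abs(rec$error_deg),
             reward = rec$reward,
             non_response = rec$non_response > 0,
             n_out_gated = rec$n_out_gated,
             lag = rec$lag,
             ocv = rec$ocv,
             max_load = TRUE,
             n_occupied = rowSums(occ),
             all_occupied = rowSums(occ) == fit$config$n_stripes,
             occ)
}

#' Histogram of recall errors with mixture summary
#'
#' Bins signed recall errors over `(-180, 180]` and summarizes the error
#' distribution with a zero-centered wrapped-normal plus uniform mixture fit:
#' the uniform weight estimates the guess mass, and the central-bin density
#' the rate of precise recall.
#'
#' @param errors_deg signed errors in degrees.
#' @param binwidth bin width in degrees (must divide 360).
#' @return list with `breaks`, `counts`, `density`, `zero_bin_density`
#'   (proportion of trials within half a bin of zero), and the mixture fit
#'   (`guess_weight`, `sd_deg`).
#' @export
error_histogram <- function(errors_deg, binwidth = 10) {
  stopifnot(360 %% binwidth == 0)
  breaks <- seq(-180, 180, by = binwidth)
  h <- graphics::hist(errors_deg, breaks = breaks, plot = FALSE)
  fit <- fit_error_mixture(errors_deg)
  list(breaks = breaks, counts = h$counts, density = h$density,
       zero_bin_density = mean(abs(errors_deg) <= binwidth / 2),
       guess_weight = fit$guess_weight, sd_deg = fit$sd_deg)
}

#' Fit a guess + precise-memory mixture to signed errors
#'
#' Maximum-likelihood fit of `w * Uniform(-180, 180] +
#' (1 - w) * WrappedNormal(0, sd)` to signed recall errors (degrees). The
#' uniform weight `w` is the guess mass; the wrapped-normal SD measures the
#' precision of non-guess responses.
#'
#' @param errors_deg signed errors in degrees.
#' @return list with `guess_weight`, `sd_deg`, `loglik`, `converged`.
#' @export
fit_error_mixture <- function(errors_deg) {
  e <- errors_deg[is.finite(errors_deg)]
  stopifnot(length(e) >= 10)
  wrapped_dnorm <- function(x, sd) {
    d <- 0
    for (k in -2:2) d <- d + stats::dnorm(x + 360 * k, 0, sd)
    d
  }
  # the precision component is bounded at 60 degrees: beyond that a wrapped
  # normal is close enough to uniform that the mixture weight is no longer
  # identified, and memory precision components are far narrower in practice
  nll <- function(par) {
    w <- stats::plogis(par[1]); sd <- exp(par[2])
    if (sd < 1 || sd > 60) return(1e10)
    ll <- sum(log(w / 360 + (1 - w) * wrapped_dnorm(e, sd)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::optim(c(0, log(20)), nll, method = "Nelder-Mead")
  list(guess_weight = stats::plogis(fit$par[1]),
       sd_deg = exp(fit$par[2]),
       loglik = -fit$value, converged = fit$convergence == 0)
}

#' Stripe usage on maximal-load store trials
#'
#' On the store trials where the maximum number of stimuli has been
#' presented, the per-stripe occupancy rates, the proportion of trials with
#' all stripes occupied, and the proportion with at least one empty stripe
#' (the behavioral signature of "giving up").
#'
#' @param eval_log evaluation log from [evaluate_network()] (rows from
#'   several seeds may be pooled).
#' @return list with `per_stripe` rates, `all_occupied_rate`,
#'   `empty_stripe_rate`, and `n_trials`.
#' @export
stripe_usage <- function(eval_log) {
  ml <- eval_log[eval_log$max_load, , drop = FALSE]
  occ_cols <- grep("^occ\\.", names(ml), value = TRUE)
  list(per_stripe = colMeans(ml[occ_cols]),
       all_occupied_rate = mean(ml$all_occupied),
       empty_stripe_rate = mean(!ml$all_occupied),
       n_trials = nrow(ml))
}

#' Mean absolute recall error by out-of-cluster variance bin
#'
#' @param eval_log evaluation log (set size 3+; rows with undefined OCV are
#'   dropped).
#' @param breaks OCV bin edges in degrees.
#' @return data.frame with `ocv_bin` (factor), `ocv_mid`, `mean_abs_err`,
#'   `n`.
#' @export
ocv_binned_error <- function(eval_log, breaks = c(0, 20, 40, 60, 80, 120)) {
  ok <- is.finite(eval_log$ocv)
  d <- eval_log[ok, , drop = FALSE]
  bin <- cut(d$ocv, breaks = breaks, include.lowest = TRUE)
  agg <- stats::aggregate(d$abs_err, list(ocv_bin = bin), mean)
  names(agg)[2] <- "mean_abs_err"
  cnt <- table(bin)
  agg$n <- as.integer(cnt[as.character(agg$ocv_bin)])
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  agg$ocv_mid <- mids[match(as.character(agg$ocv_bin), levels(bin))]
  agg
}

#' Mean absolute recall error by recency lag
#'
#' Lag is the number of trials between the presentation of the probed item
#' and the recall probe (1 = probed item was the last one presented).
#'
#' @param eval_log evaluation log.
#' @return data.frame with `lag`, `mean_abs_err`, `n`.
#' @export
recency_curve <- function(eval_log) {
  agg <- stats::aggregate(eval_log$abs_err, list(lag = eval_log$lag), mean)
  names(agg)[2] <- "mean_abs_err"
  agg$n <- as.integer(table(eval_log$lag)[as.character(agg$lag)])
  agg
}

#' Train a battery of seeds for one configuration
#'
#' Convenience wrapper used by the analysis scripts and tests: trains
#' `n_seeds` independent networks and pools their frozen-weights evaluation
#' logs.
#'
#' @param model,n_stripes,set_size,epochs,trials_per_epoch,eval_episodes,
#'   burst_gain,dip_gain,params passed to [run_config()].
#' @param n_seeds number of random initializations.
#' @param base_seed seeds are `base_seed * 1000 + 1:n_seeds`.
#' @return list with `fits` (list of `pbwm_fit`), `eval` (pooled evaluation
#'   log with a `seed` column), and `config`.
#' @export
train_battery <- function(model, set_size, n_seeds = 10, n_stripes = 2,
                          epochs = 120, trials_per_epoch = 100,
                          eval_episodes = 100, base_seed = 1,
                          burst_gain = NULL, dip_gain = NULL,
                          params = pbwm_params()) {
  config <- run_config(model = model, n_stripes = n_stripes,
                       set_size = set_size, epochs = epochs,
                       trials_per_epoch = trials_per_epoch,
                       eval_episodes = eval_episodes,
                       burst_gain = burst_gain, dip_gain = dip_gain,
                       params = params)
  seeds <- base_seed * 1000 + seq_len(n_seeds)
  fits <- lapply(seeds, function(s) train_network(config, s))
  evals <- lapply(seq_along(fits), function(i) {
    ev <- evaluate_network(fits[[i]], n_episodes = eval_episodes,
                           seed = seeds[i] + 500000L)
    ev$seed <- seeds[i]
    ev
  })
  list(fits = fits, eval = do.call(rbind, evals), config = config)
}

#' Dopamine burst/dip gain sweep
#'
#' Trains a reduced seed battery for each cell of a burst-gain by dip-gain
#' grid and reports the mean absolute recall error and stripe usage per
#' cell.
#'
#' @param burst_grid,dip_grid numeric gain grids.
#' @param model,set_size,n_stripes,n_seeds,epochs,eval_episodes battery
#'   settings per cell.
#' @param base_seed battery seed offset.
#' @return data.frame with one row per cell: `burst_gain`, `dip_gain`,
#'   `mean_abs_err`, `all_occupied_rate`, `empty_stripe_rate`,
#'   `nonresp_rate`.
#' @export
da_sweep <- function(burst_grid = c(0.5, 1, 1.5), dip_grid = c(0.5, 1, 1.5),
                     model = "chunk", set_size = 2, n_stripes = 2,
                     n_seeds = 4, epochs = 200, eval_episodes = 100,
                     base_seed = 1) {
  cells <- expand.grid(burst_gain = burst_grid, dip_gain = dip_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    b <- train_battery(model, set_size, n_seeds = n_seeds,
                       n_stripes = n_stripes, epochs = epochs,
                       eval_episodes = eval_episodes,
                       base_seed = base_seed + i,
                       burst_gain = cells$burst_gain[i],
                       dip_gain = cells$dip_gain[i])
    su <- stripe_usage(b$eval)
    data.frame(burst_gain = cells$burst_gain[i], dip_gain = cells$dip_gain[i],
               mean_abs_err = mean(b$eval$abs_err),
               all_occupied_rate = su$all_occupied_rate,
               empty_stripe_rate = su$empty_stripe_rate,
               nonresp_rate = mean(b$eval$non_response))
  })
  do.call(rbind, res)
}

#' Success probability of random gating
#'
#' Probability that uniformly random input- and output-gating stores the
#' first presented item un-overwritten and reads it out correctly, in a
#' network with `n` stripes and `N` sequentially presented items:
#' `(n - 1)^(N - 1) / n^N`. The first item lands in some stripe; each of the
#' remaining `N - 1` items must avoid that stripe (`(n-1)/n` each), and the
#' readout must pick the right stripe (`1/n`).
#'
#' @param n_stripes number of stripes (`n >= 1`).
#' @param set_size number of items presented (`N >= 1`).
#' @return probability in `[0, 1]`.
#' @export
guess_probability <- function(n_stripes, set_size) {
  stopifnot(n_stripes >= 1, set_size >= 1)
  (n_stripes - 1)^(set_size - 1) / n_stripes^set_size
}

#' Exhaustive enumeration oracle for random-gating success
#'
#' Enumerates every equally likely combination of input-gate assignments
#' (each of `N` items into one of `n` stripes, later items overwriting) and
#' output-gate choices (one of `n` stripes), and counts the combinations in
#' which the first item survives un-overwritten and is the one read out.
#' Brute-force cross-check for [guess_probability()].
#'
#' @inheritParams guess_probability
#' @return exact success probability.
#' @export
enumerate_gating_success <- function(n_stripes, set_size) {
  stopifnot(n_stripes >= 1, set_size >= 1)
  assign <- as.matrix(expand.grid(rep(list(seq_len(n_stripes)), set_size)))
  survives <- apply(assign, 1, function(a) {
    set_size == 1 || all(a[-1] != a[1])
  })
  # each surviving assignment succeeds for exactly one of the n readout choices
  sum(survives) / (nrow(assign) * n_stripes)
}
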