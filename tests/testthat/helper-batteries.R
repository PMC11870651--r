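# Shared trained-network batteries for the integration/acceptance tests.
# Training is the expensive step, so batteries are computed once per test run
# and cached; every consumer states the battery it uses.
#
# Scale: 16 seeds x 500 epochs (100 trials each) per configuration, with a
# 200-episode frozen evaluation per seed (the compiled engine makes the full
# reference regimen affordable).

.battery_cache <- new.env(parent = emptyenv())

get_battery <- function(model, set_size, n_stripes = 2, n_seeds = 16,
                        epochs = 500, eval_episodes = 200, base_seed = 101) {
  key <- paste(model, set_size, n_stripes, n_seeds, epochs, base_seed,
               sep = "_")
  if (!is.null(.battery_cache[[key]])) return(.battery_cache[[key]])
  b <- train_battery(model, set_size, n_seeds = n_seeds,
                     n_stripes = n_stripes, epochs = epochs,
                     eval_episodes = eval_episodes, base_seed = base_seed)
  .battery_cache[[key]] <- b
  b
}

final_alpha_gap <- function(battery) {
  # alpha(chunk stripe) - alpha(input stripe) at the end of training, per seed
  vapply(battery$fits, function(f) {
    el <- f$epoch_log
    n <- nrow(el)
    src <- f$net$stripe_source
    a <- as.numeric(el[n, paste0("alpha.", seq_along(src))])
    mean(a[src == "chunk"]) - mean(a[src == "input"])
  }, numeric(1))
}
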