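# pbwmchunk

A simulator for a prefrontal cortex / basal ganglia working memory (PBWM)
circuit augmented with an adaptive chunking layer, together with the
continuous-report color-wheel task used to study visual working memory
capacity.

## The scientific problem

Working memory capacity looks slot-like in some experiments (items are
either recalled precisely or guessed) and resource-like in others
(precision degrades with load). This package implements a circuit-level
account that produces both regimes from one mechanism. Memory slots are PFC
"stripes" — isolated populations storing colors as Gaussian activity bumps
on a 20-unit ring. A striatal Go/NoGo module per stripe decides, per
stimulus, whether to load it into the stripe (input gating) and, at recall,
which stripe to read out (output gating); the gating policy is learned from
dopaminergic reward prediction errors with eligibility traces. A posterior
"chunk" layer receives the current stimulus bottom-up and all maintained
PFC bumps top-down: when the stimulus lies close to a maintained item the
settled attractor merges them, so the network can learn to *chunk* — store
the merged, less precise representation and keep its other stripe free —
whenever task demands (set size) make that worthwhile.

Core quantities, in the field's standard notation:

- rate code `y = 1 / (1 + 1/(gamma [g_e - g_e^Theta]+))` over point neurons
  with FFFB pooled inhibition `g_i = G_i (ff + fb)`;
- population-vector decoding of ring activity, signed circular errors in
  degrees on (-180, 180];
- reward `r = 1 - |error|/45`, reward prediction error `delta = r - V` with
  a Rescorla-Wagner critic, dopamine gains scaling bursts (`delta > 0`) and
  dips (`delta < 0`) separately;
- gating policy metric `alpha_j = [(sum Go - sum NoGo)/(sum Go + sum NoGo)]+`
  per stripe over the orientation inputs;
- random-gating baseline `P(correct) = (n-1)^(N-1) / n^N` for `n` stripes
  and `N` sequentially stored items.

See `vignette("pbwm-chunking-methods")` for the full model description and
every design decision.

## A worked example

Train a two-stripe chunking network on set-size-2 episodes and look at what
it learned:

```r
library(pbwmchunk)

cfg <- run_config(model = "chunk", n_stripes = 2, set_size = 2,
                  epochs = 300)
fit <- train_network(cfg, seed = 42)
fit
#> pbwm_fit: chunk model, 2 stripes, set size 2, 300 epochs (seed 42)
#>   final mean |error| 37.4 deg, non-response rate 0.00

ev <- evaluate_network(fit, n_episodes = 150, seed = 9)
stripe_usage(ev)$all_occupied_rate   # both stripes loaded at full load
#> [1] 0.9933333
mean(ev$n_out_gated[ev$n_out_gated > 0])  # stripes read out per response
#> [1] 1.38
fit_error_mixture(ev$error_deg)$guess_weight  # uniform "guessing" mass
#> [1] 0.04534467
guess_probability(2, 1)  # random-gating baseline, single item, two stripes
#> [1] 0.5
```

After training, the network loads both stripes on 99% of maximal-load
trials and almost never guesses (4.5% uniform mass, against a 50%
random-gating baseline for a single stored item). This particular seed
still reads out both stripes on some recalls (1.38 on average — their
output drives are close and the read-out blend decodes to the right value
once both stripes usually hold related content); across seed batteries the
average is close to one stripe per response. The final-epoch training error
(37 deg) is the noisy online figure over one epoch's 33 episodes; the
frozen evaluation is the number to read. Longer, many-seed batteries as in
`train_battery()` give the stable averages.

Analysis helpers operate on pooled evaluation logs: `error_histogram()`,
`stripe_usage()`, `ocv_binned_error()` (recall error by the circular spread
of the non-probed items), `recency_curve()`, `da_sweep()` (performance over
a dopamine burst-gain by dip-gain grid), and `gating_policy_metric()`.

Command-line entry points (thin wrappers over these functions) live in
`inst/scripts/`: `pbwm_train.R` writes a self-describing run directory
(config snapshot, epoch log, evaluation log CSV, weights, summary JSON) and
`pbwm_analyze.R` dispatches the analyses over one or more run directories.

The evaluation log (`eval_log.csv`, one row per recall probe) has columns
`episode`, `error_deg` (signed, degrees), `abs_err`, `reward`,
`non_response`, `n_out_gated`, `lag` (trials between presentation of the
probed item and recall), `ocv` (circular spread of the non-probed items,
degrees; `NA` below set size 3), `max_load`, `n_occupied`, `all_occupied`,
and per-stripe occupancy flags `occ.1 ... occ.n` measured on the episode's
final store trial. The epoch log has per-epoch `mean_abs_err`,
`nonresp_rate`, `mean_reward`, and the gating-policy metric `alpha.j` per
stripe.

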