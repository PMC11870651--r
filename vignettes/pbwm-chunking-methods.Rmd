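---
title: "A chunk-augmented prefrontal-basal ganglia working memory circuit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chunk-augmented prefrontal-basal ganglia working memory circuit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbwmchunk)
```

## The problem

Visual working memory (WM) experiments with continuous report — remember a
few colored, oriented bars; later reproduce the color cued by one
orientation on a color wheel — produce error distributions that mix a
precise component centered on zero with a uniform "guessing" component.
Slots accounts attribute the uniform mass to items that never got a slot;
resource accounts attribute broad errors to precision dropping with load. A
third possibility is *adaptive chunking*: similar items can be merged into
one shared, less precise representation, freeing capacity for other items.

`pbwmchunk` implements a prefrontal cortex / basal ganglia working memory
(PBWM) circuit extended with a chunking layer, and the continuous-report
task harness needed to study it. Memory slots are PFC "stripes" —
anatomically isolated populations that are updated (input gating) and read
out (output gating) under the control of striatal Go/NoGo modules, which
learn their gating policies from dopaminergic reward prediction errors
(RPEs). Chunking is not hard-wired: the network can learn to store either
the raw stimulus or its merger with the nearest maintained item, depending
on what the task rewards.

## Neurons, layers, and the population code

All layers use rate-coded point neurons. The membrane potential integrates
excitatory, inhibitory, and leak currents toward the conductance-weighted
mean of their reversal potentials,

$$C_m \frac{dV_m}{dt} = g_e \bar g_e (E_e - V_m) + g_i \bar g_i (E_i - V_m)
  + \bar g_l (E_l - V_m),$$

with normalized potentials (inhibitory reversal 0.25, leak 0.3, threshold
$\Theta = 0.5$, excitatory reversal 1). The communicated rate is a
thresholded saturating function of the excess excitatory conductance,

$$y = \frac{1}{1 + 1/(\gamma\,[g_e - g_e^\Theta]_+)},\qquad
  g_e^\Theta = \frac{g_i \bar g_i (E_i - \Theta) + \bar g_l (E_l - \Theta)}
  {\Theta - E_e},$$

where $g_e^\Theta$ is the drive that would put the equilibrium potential
exactly at threshold. The form of the rate function is ambiguous as
sometimes printed; we use the standard form above (reciprocal of one plus
the reciprocal drive). Integration is explicit Euler with an effective rate
constant of 0.3 per cycle; layers settle for at most 50 cycles with early
stopping when no activity moves by more than $10^{-4}$ (typical settles
converge in 10–25 cycles). The settling core is compiled (Rcpp) because it
runs once or more per simulated trial.

Layer inhibition is pooled FFFB: a single inhibitory conductance
$g_i = G_i\,(\mathrm{ff} + \mathrm{fb})$, with the feedforward term tracking
the layer's mean net input above a floor and the feedback term tracking its
mean firing rate through a single-cycle exponential average (time constant
0.5) — the averaging prevents inhibitory ringing in 20-unit layers.

Colors live on $[0, 2\pi)$ and are encoded as circular-Gaussian bumps over a
20-unit ring whose preferred colors tile the circle. The bump width
($\sigma = 0.72$ rad) is set so that on average 10 of 20 units exceed
activity 0.1 — the coarse-coding regime the circuit assumes. Decoding is a
population vector (the angle of the activity-weighted resultant); its
normalized length serves as a confidence, and activity with resultant below
0.05 is *non-decodable*, which is how non-responses are detected.
Orientations are discrete one-hot codes (4 by default, the maximum set
size).

## The chunk layer

The chunk layer is a posterior ring that receives the sensory bump
bottom-up (relative scale 1) and every maintained PFC bump top-down
(relative scale 0.5 each), through fixed topographic circular-Gaussian
weights (width 0.45 rad). Convergent excitation means that a maintained
bump overlapping the current input reinforces the overlap, pulling the
settled attractor toward the nearest neighbor; FFFB inhibition suppresses
maintained bumps that are too far away to overlap.

The resulting *chunking profile* — decoded deviation of the settled chunk
representation from the input, as a function of the input's offset from the
nearest maintained item — is zero at zero offset, rises to a peak of about
15 degrees near a 60-degree offset, and collapses to zero beyond roughly
120 degrees. The bottom-up:top-down ratio and the chunk layer's inhibitory
gain ($G_i = 2.2$) were calibrated against the shape constraints (interior
peak at an intermediate offset, near-zero deviation at large offsets,
attraction restricted to the nearest neighbor) plus one mechanism-level
requirement — a merged item must retain a usable trace of the absorbed
neighbor, else chunking cannot confer any recall benefit — and then frozen;
a regression test pins the full curve. Raising `pfc_scale` widens and
raises the attraction region — a network with stronger top-down projections
chunks more liberally.

One idealization: when a stripe stores chunk-layer content, its deep
maintenance layer stores the canonical re-encoded bump of the *decoded*
merged value rather than the raw settled activity. The merge angle comes
entirely from the settled chunk dynamics; the re-encoding models attractor
maintenance (the deep layer is itself a ring attractor that would
re-normalize the bump) and keeps read-out statistics uniform across
stripes.

## Stripes, gating, and the striatal policy

Each stripe has a transient superficial layer (always reflecting its source
— the sensory input for input stripes, the chunk layer for the chunk
stripe) and a deep maintenance layer. Maintenance is lossless: deep content
persists unchanged until overwritten or cleared — recency effects in this
model arise from gating-driven overwriting and chunking, not passive decay.

Gating decisions are made per stripe by striatal modules. The control input
seen by every Go/NoGo unit is the concatenation of the one-hot orientation,
a store bit, a recall bit, and the per-stripe occupancy summary. A gate
fires when its noisy Go-minus-NoGo drive is positive (Gaussian exploration
noise, SD 0.2). Input gating loads the stripe's superficial content into
maintenance, overwriting what was there; output gating copies maintenance
content to the output side, and the response ring settles from the
scale-weighted average of all gated output bumps through per-stripe plastic
mappings.

Output gating additionally passes through a pallidal competition stage:
each stripe's drive is reduced by 0.6 times the strongest positive drive
among its rivals. Read-out therefore tends to select a single maintained
representation — the biological arrangement in which BG output selects one
thalamocortical channel — while still permitting parallel read-out when
several drives are comparable (which is exactly what over-allocated
networks with many stripes do, producing "contaminated" blended responses).
Input gating is uncompeted: the same stimulus may be loaded into several
stripes at once, and trained two-stripe networks do exactly that at low
load, which is why both stripes end up occupied on essentially every
trial.

## Reinforcement learning of the gating policy

At recall the network earns reward $r = 1 - |e|/45$ for signed circular
error $e$ in degrees: +1 at zero error, zero exactly at the 45-degree
closeness threshold, negative beyond it. A non-response (nothing gated out,
or the blended response non-decodable) is scored by substituting a uniform
random report, mimicking guessing. A Rescorla–Wagner critic tracks expected
reward ($\alpha_V = 0.05$), and the RPE $\delta = r - V$ is scaled
asymmetrically by the dopamine gains: `burst_gain` multiplies positive
$\delta$, `dip_gain` negative $\delta$. The critic starts at the
uniform-guesser baseline ($1 - 90/45 = -1$) so that early RPEs measure
deviation from chance rather than the critic's own ignorance.

Credit assignment uses eligibility traces: when a gate fires, its synapses
are tagged with the current control-input activity; tags decay by 0.9 per
trial and are cleared after each reward delivery. The three-factor update is

$$\Delta w_{Go} = +\eta\,\delta_{\mathrm{eff}}\,\mathrm{tag}, \qquad
  \Delta w_{NoGo} = -\eta\,\delta_{\mathrm{eff}}\,\mathrm{tag},$$

with $\eta = 0.02$ and weights clipped to $[0,1]$: bursts reinforce the Go
pathway of recently used gates, dips reinforce their NoGo opposition.

Two stabilizing mechanisms proved necessary and are part of the model's
design:

* **Opponent credit for withheld gates.** A gate that was evaluated but did
  *not* fire stamps a complementary suppression tag, applied with the
  opposite sign at a quarter of the weight of a fire tag
  (`suppress_scale = 0.25`). With no suppression credit at all, "never
  fire" is an absorbing state — no tags, no learning signal, no way back —
  and every network eventually collapses into permanent non-response; with
  full symmetric credit, withholding is never worth it and the
  non-response/"giving up" regime that sparse reward should produce
  disappears. The intermediate weight keeps gating recoverable while
  preserving that regime (about a fifth of chunk-model recalls at set size
  4 are non-responses).
* **Slow forgetting of gate weights.** All Go/NoGo weights decay
  multiplicatively by 0.0003 per reward event. A gating route that was
  punished early (for example, one orientation's input gate dying during a
  bad phase) would otherwise sit at a drive so negative that exploration
  noise can never revisit it; the decay returns stagnant routes to the
  explorable region over a few thousand episodes while leaving actively
  reinforced routes untouched.

The learned policy is summarized per stripe by the rectified normalized
contrast $\alpha_j = [(\sum Go - \sum NoGo)/(\sum Go + \sum NoGo)]_+$ over
the orientation block of the input-gating weights; $\alpha_j \in [0,1]$,
zero whenever NoGo dominates. Its per-epoch trace is the gating-policy
trajectory reported by `train_network()`.

## The supervised response pathways

Two mappings are plastic: input ring to response ring (exercised on every
store trial — the network must report the color it currently sees) and each
PFC output stripe to the response ring (exercised at recall). Both learn a
two-phase contrastive delta rule: settle the response (expectation phase),
clamp the target bump (outcome phase, amplitude 0.85 — matched to the
attainable settled activity so the rule has a reachable fixed point), and
move each weight by presynaptic activity times the outcome-minus-expectation
difference (learning rate 0.05, weights in $[0,1]$).

The read-out mappings inevitably see mismatched training pairs — whenever
the wrong stripe is read out, the presynaptic bump and the clamped target
disagree. Mismatches are angularly uniform, so their net effect is a
diffuse potentiation that would slowly saturate the mapping toward a flat,
undecodable state. A small multiplicative decay (0.002 per training event)
opposes the diffuse component while consistent correlations maintain
themselves; this plays the role of the homeostatic (sliding-threshold)
component of fully specified error-driven cortical learning rules. The
read-out mapping trains whenever content was gated out, including trials
whose blended response fell below the decode floor — otherwise the pathway
cannot bootstrap from random weights.

## Task, episodes, and the training regimen

An episode presents `set_size` store trials — independent uniform colors on
the circle, distinct orientations — followed by one recall probe of a
uniformly chosen presented orientation. Each condition's orientation
inventory equals its set size (a set-size-2 network sees two possible
orientations): the orientations exist to cue presented items, and with an
inventory larger than the stripe count even the optimal policy would face
unresolvable probe-to-stripe collisions at low load, contrary to the
near-perfect low-load behavior this circuit exhibits. Maintenance is cleared between
episodes: a recall probe ends the sequence, and the "into subsequent
trials" persistence the circuit provides is within-episode. Epochs pack
`round(100/(set_size+1))` episodes so that 100 store-plus-recall events
constitute one epoch; the reference regimen is 500 epochs, and reduced
regimens used by the test suite are stated where they run. Non-probed
items' similarity is measured by the out-of-cluster variance (OCV),
computed as the circular standard deviation
$\sqrt{-2\ln R}\cdot 180/\pi$ of the other items' colors, where $R$ is
their mean resultant length; low OCV means chunkable companions.

Error distributions are summarized by a maximum-likelihood mixture of a
zero-centered wrapped normal (precision component) and a uniform component
whose weight estimates the guess mass.

## What the generator does and does not emulate

The synthetic task reproduces the structure of continuous-report
experiments: sequential presentation, role-addressable probing by
orientation, uniform color statistics, and chance-level scoring of
non-responses. It does not emulate perceptual encoding noise, stimulus
timing, motor response noise on the wheel, or trial-to-trial attentional
fluctuations; passing tests therefore speak to the circuit-level account
(gating, chunking, credit assignment), not to quantitative fits of any
human dataset.

## Scales used by the shipped analyses

The packaged tests and the acceptance script train 10-seed batteries at the
full 500-epoch regimen (100 trials per epoch; the compiled engine runs one
network in a few seconds), with 200 frozen evaluation episodes per seed,
and verify the qualitative claims (directions, orderings, rates) rather
than curve-level detail. The dopamine-gain sweep uses a coarse 3 by 3 gain
grid with a reduced battery per cell. Larger seed batteries (the reference
analyses average 80+) are available through `train_battery()`.

## Numerical choices and degenerate inputs

* Settling tolerance $10^{-4}$ on the maximum activity change; cycle
  budgets 50 (chunk layer) and 30 (response layer).
* Signed errors live on $(-180, 180]$; an exact antipodal tie maps to
  +180.
* All-zero or perfectly symmetric activity decodes as non-decodable rather
  than erroring; OCV is flagged undefined (`NA`) with fewer than two other
  items; `gen_episode()` rejects set sizes below 2 or above the number of
  orientations.
* The response layer is silent (no settling) when its drive peak is below
  0.005.
* Ties in gating are measure-zero under Gaussian noise; a drive of exactly
  zero does not fire.

## Known limitations

* A single chunk layer with fixed top-down strength: the network cannot
  tune its own chunking threshold; a reservoir of chunk layers with varying
  thresholds is out of scope.
* Discrete orientation probes only; no continuous orientation report and no
  2-D feature-conjunction codes.
* The supervised pathways use a contrastive delta rule with homeostatic
  decay, not a fully parameterized biological learning rule; only its
  error-driven contract is claimed.
* Striatal modules are two learned weight vectors per stripe and gate type
  with a scalar competition stage, not spiking or multi-unit pallidal
  dynamics.
* Between-seed variance of trained behavior is substantial even at the
  500-epoch regimen; individual seeds can and do land in poorer local
  optima, and pooled rates (stripe occupancy, non-response) move by several
  points between seed batteries smaller than the reference scale.
* The advantage of chunking beyond allocated capacity expresses itself here
  as a reduction in guess mass with a broader precise component; the
  central error bin itself is not taller for chunk networks, because merged
  items are recalled with 10-40 degree errors.
* The learned occupancy-avoidance policy protects the first-stored item, so
  serial-position curves are inverted-U (primacy and recency, middle items
  worst) rather than monotonically recency-dominated.
* The orientation-block gating-policy contrast ($\alpha_j$) rectifies to
  near zero for the partitioned policies this model learns, so policy-trace
  analyses based on it separate stripes only weakly.
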