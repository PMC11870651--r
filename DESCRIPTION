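Package: pbwmchunk
Title: Adaptive Chunking in a Prefrontal-Basal Ganglia Working Memory Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator for a prefrontal cortex / basal ganglia working memory
    (PBWM) circuit extended with an adaptive chunking layer. Colors are stored
    as Gaussian population bumps on a ring of rate-coded point neurons with
    feedforward/feedback (FFFB) pooled inhibition; striatal Go/NoGo modules
    learn input- and output-gating policies through dopamine-modulated
    reinforcement learning with eligibility traces; a posterior attractor layer
    merges incoming stimuli with the nearest maintained prefrontal
    representation, implementing chunking as lossy compression. Includes a
    continuous-report color-wheel task generator, a training and evaluation
    harness, and the analysis suite (error-mixture fits, out-of-cluster
    variance, stripe usage, gating-policy traces, dopamine gain sweeps,
    recency curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
LinkingTo: Rcpp
Config/testthat/edition: 3
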