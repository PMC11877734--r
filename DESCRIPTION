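Package: rwlearn
Title: Rescorla-Wagner Modelling of Probabilistic Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulators and computational models for three
    probabilistic learning tasks used to compare learning in autistic and
    non-autistic adults: a single-cue probabilistic learning task, a
    multi-cue probabilistic learning task, and a two-armed bandit
    reinforcement learning task. Implements three Rescorla-Wagner model
    variants (simple, dual learning rate, counterfactual), per-participant
    maximum-likelihood and hierarchical Bayesian estimation (via JAGS),
    Pareto-smoothed importance-sampling leave-one-out cross-validation
    (PSIS-LOO) model comparison, signal-detection scoring, accuracy
    summaries, and a synthetic two-group cohort generator for parameter-
    and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
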