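Package: avoidrl
Title: Reinforcement Learning Models of Instrumental Avoidance in a
    Probabilistic Reversal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of a two-option
    probabilistic reversal task in which people learn to avoid a social
    threat cue. Provides a task/agent simulator (random, oracle,
    fixed-side and Q-learning agents with a habit kernel), sequence
    likelihoods for simple and counterfactual delta-rule learning models,
    per-subject maximum a posteriori fitting under gamma/beta priors,
    posterior-predictive simulation, parameter- and model-recovery
    studies, behavioral summary statistics (hit rates, hyperbolic
    learning curves, win-stay/lose-shift, exclusion filters, subjective
    rating summaries), and nonparametric model comparison (Friedman and
    Wilcoxon tests with rank-biserial effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
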