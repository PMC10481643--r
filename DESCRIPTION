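Package: foragefit
Title: Hierarchical Reinforcement-Learning Analysis of Odor-Guided Serial
    Choice Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses rodent odor-guided serial choice
    (four-odor foraging) sessions. Provides the task rules (8-of-10
    criterion, omission and reminder bookkeeping), a softmax Q-learning
    model of trial-by-trial odor choice with phase-specific learning
    rates and inverse temperatures and shared initial odor values, a
    hierarchical Bayesian fitting engine with WAIC model comparison,
    credible-interval group contrasts and posterior-predictive checks, a
    generative cohort simulator for parameter- and model-recovery
    studies, descriptive behavioral summaries (choices to criterion,
    nonrewarded choice breakdowns, reward accumulation, single-entry
    choices), and a rotational-bias scoring pipeline for pose-tracked
    head/torso/tail-base coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
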