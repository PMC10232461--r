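Package: taskspike
Title: Spike-Train Analysis for Self-Paced Pedal-Release Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing extracellular spike trains recorded while
    head-fixed rodents perform a self-paced, uncued left/right pedal-release
    task. Provides a tabular session data model with validation, a synthetic
    session generator (behaviour, pedal traces, inhomogeneous-Poisson neuron
    archetypes, antidromic stimulation with collision physics), peri-event
    time histograms, Kolmogorov-Smirnov task-relevance testing, the
    Hold/Go/Reward task taxonomy with the holding-time intersection-slope
    classifier, laterality and reward-modulation indices, stepwise
    generalized-linear-model classification of time versus pedal coding,
    Gaussian-mixture clustering of event-peak latencies with BIC model
    selection and an x-means cross-check, bootstrap pseudo-signal-flow
    analysis between regions, and collision-test identification of
    projection neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pROC,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
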