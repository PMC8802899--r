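Package: spinalsynergy
Title: Spinal Circuit Simulation and Muscle Synergy Analysis for Isometric Knee Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how limb position shapes muscle synergies in an
    isometric knee-extension task. Provides a Monte-Carlo simulator for a small
    spinal circuit of exponential integrate-and-fire neuron populations driven
    by cortical and proprioceptive afferent inputs, a surface-EMG style
    preprocessing and nonnegative matrix factorization (NMF) synergy pipeline
    with variance-accounted-for rank selection, a seeded synthetic sEMG cohort
    generator with exported ground truth, and the statistical contrasts and
    model-versus-data trend checks used to compare simulated motor-neuron
    activity with recorded muscle activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    signal,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
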