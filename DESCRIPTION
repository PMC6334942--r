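Package: saccadapt
Title: Simulation and Dual-State Analysis of Global Saccadic Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate and analyse global saccadic adaptation
    experiments in which targets arranged on a hexagonal path are displaced
    during the saccade to drive gain-up or gain-down adaptation. Provides a
    synthetic-session generator (dual-state trial-by-trial gain dynamics,
    main-sequence-realistic gaze traces, blinks and outliers), median-based
    velocity-threshold saccade detection, trial quality control and gain
    normalisation, exponential timescale fits with paired participant
    bootstrap comparisons, and dual-state (fast/slow process) gain
    decomposition with fixed learning and retention rates, plus the summary
    statistics and report bundle of the accompanying analysis workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
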