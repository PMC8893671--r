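Package: affectloop
Title: Simulation and Analysis of Closed-Loop Decoded-Affect Neurofeedback
    Experiments
Version: 0.1.0
Authors@R:
    person("BIRC", "Computational", email = "affectloop@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse closed-loop real-time fMRI
    experiments in which multivariate decodings of affective valence and
    arousal drive stimulus delivery. Provides a synthetic-data generator
    with planted voxel-pattern encodings and double-gamma hemodynamics,
    valence/arousal stimulus-catalog sampling (maximal-span and
    arousal-matched polar subsets), linear max-margin decoders with Platt
    probability calibration and beta-series extraction, a streaming
    feedback/trigger state machine with threshold decay and emergency
    default, Haufe-transform encoding maps with permutation nulls,
    surrogate resting-state control trials, and mixed-effects analyses of
    affect-processing bias with parameter-recovery and calibration
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
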