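Package: resteeg
Title: Automated Resting-State EEG Preprocessing and Feature Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated, scriptable pipeline for resting-state EEG:
    BIDS-organized BrainVision/EDF ingestion, seven-stage preprocessing
    (line-noise regression, high-pass filtering and bad-channel rejection,
    average re-referencing, ICA with heuristic component classification and
    a repetition-stabilized bad-segment mask, spherical-spline channel
    interpolation, artifact-subspace bad-segment removal, overlapping
    epoching), and five feature-extraction stages (Slepian multitaper power
    spectra, alpha peak frequency, LCMV beamformer source reconstruction
    onto 100 atlas ROI centroids, debiased weighted phase-lag index and
    orthogonalized amplitude-envelope connectivity, and graph-theoretic
    network metrics). Includes group-level statistics (1-D cluster-based
    permutation tests over frequencies and JZS Bayes-factor t-tests), a
    synthetic-EEG generator with ground-truth manifests for end-to-end
    verification, and per-recording HTML reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tools,
    signal,
    igraph,
    jsonlite,
    rhdf5,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
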