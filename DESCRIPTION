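Package: netlong
Title: Longitudinal Network-Based Statistics for Partial-Correlation Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds Fisher z-transformed partial-correlation connectomes from
    region-of-interest (ROI) time series and performs network-based statistical
    inference on them. Cross-sectional edge-behavior associations are tested with
    an edge-wise general linear model, a fixed statistic threshold, and
    permutation family-wise error control on connected-component strength;
    longitudinal session effects are tested with edge-wise linear mixed models
    (random intercept per subject) and restricted within-subject permutations,
    followed by estimated-marginal-means post hoc session contrasts with
    Benjamini-Hochberg false-discovery-rate correction. Includes the signal
    cleaning steps typical of resting-state functional MRI (initial volume
    discard, nuisance eigenvector and motion regression, zero-phase band-pass
    filtering, box smoothing), dual regression of group spatial maps with paired
    sign-flip permutation tests, behavioral statistics for pair-bonding assays
    (partner-preference index, huddling latency, rank-based tests with effect
    sizes), and a synthetic cohort generator with known ground truth that
    emulates a longitudinal rodent imaging study design, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    emmeans,
    RNifti
Config/testthat/edition: 3
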