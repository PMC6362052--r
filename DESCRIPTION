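Package: segepi
Title: Simulation and Group Analysis of Segmented Versus Single-Shot EPI for Rodent Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom simulation of multishot (segmented) and
    single-shot echo-planar imaging (EPI) for rodent resting-state fMRI,
    together with the group-analysis chain used to compare the two
    acquisitions: B0 off-resonance distortion and signal-dropout physics,
    planted resting-state networks, confound regression and band-pass
    preprocessing, SNR and temporal-SNR quality metrics, Dice and Jacobian
    geometric-distortion metrics, threshold-free cluster enhancement (TFCE)
    with permutation-based family-wise error control, spatial ICA with dual
    regression, and Fisher-z adjacency-matrix consistency with
    noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
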