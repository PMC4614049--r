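Package: vibromap
Title: Vibrotactile Finger Mapping from ECoG by Cluster-Based Permutation
    Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for somatotopic mapping of individual fingers from
    electrocorticographic (ECoG) recordings during vibrotactile
    stimulation. Implements the full analysis chain: epoching,
    per-grid common average referencing, zero-phase FIR filtering,
    Morlet wavelet time-frequency decomposition with per-trial baseline
    normalisation to decibels, per-band cluster-based nonparametric
    permutation statistics over channel x frequency x time maps with
    family-wise error control by the maximum cluster-mass null, and
    localisation of finger representations by power-weighted cluster
    centroids. Ships a synthetic ECoG session generator with ground
    truth (1/f background, somatosensory evoked components, mid-gamma
    event-related synchronisation bursts and alpha/beta
    desynchronisation) so that every stage is testable end to end, plus
    calibration and recovery simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'io.R'
    'preprocess.R'
    'spectral.R'
    'clusters.R'
    'config.R'
    'evoked.R'
    'somatotopy.R'
    'reporting.R'
    'synthetic.R'
    'studies.R'
    'vibromap-package.R'
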