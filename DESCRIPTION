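Package: detectbms
Title: Model-Based fMRI Analysis of Near-Threshold Somatosensory Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissociates somatosensory target detection from stimulus
    intensity, detection probability, expected uncertainty, and overt
    reports by voxel-wise random-effects Bayesian model selection over
    competing parametric-modulation GLMs. Provides two-parameter logistic
    psychometric fitting and intensity-grid derivation, generation of the
    counterbalanced near-threshold detection design, a synthetic
    behaviour-plus-BOLD cohort simulator with ground truth, exact conjugate
    Bayesian GLM log-evidence maps, Dirichlet random-effects model selection
    with exceedance-probability and family-level inference, EP/cluster-extent
    thresholding, and post-selection ROI statistics (subject probability
    peaks, JZS and contingency Bayes factors, stimulus-response profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
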