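Package: mtlmvpa
Title: Searchlight MVPA Decoding of Episodic Memories in Medial Temporal Lobe ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates event-related BOLD fMRI runs with class-specific
    multivoxel patterns planted in medial-temporal-lobe-like regions of
    interest, preprocesses them (dummy-volume discard, spatial smoothing,
    linear detrending, haemodynamic-response convolution, onset shifting),
    and decodes which of three episodic memories each recall trial holds
    using ROI-restricted searchlight feature selection and a linear
    support-vector machine with error-correcting output codes under
    leave-one-trial-out cross-validation.  Includes the group-level
    statistics used to contrast decodable and non-decodable (sclerotic-like)
    regions: one-sample and paired t-tests, 2x3 repeated-measures ANOVA,
    Pearson correlation, and Dice segmentation overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
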