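Package: gfcpipe
Title: Voxel-Wise Global-Brain Functional Connectivity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for voxel-wise global-brain functional
    connectivity (GFC, also known as GBC) analysis of resting-state fMRI in
    case-control designs. Implements the standard time-series cleaning chain
    (initial-volume dropping, motion quality control, Gaussian smoothing,
    linear detrending, band-pass filtering, Friston-24 plus white-matter and
    cerebrospinal-fluid nuisance regression with the global signal retained,
    framewise-displacement scrubbing), per-voxel GFC mapping with Fisher
    z-transformed correlations, covaried voxel-wise two-sample inference with
    permutation max-statistic family-wise error control, cluster extraction,
    ROI-clinical Pearson correlation with Bonferroni correction, and
    leave-one-out RBF-SVM plus ROC biomarker evaluation. Ships a synthetic
    resting-state cohort generator so the full pipeline is testable without
    any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
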