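Package: learnconn
Title: Functional Connectivity Analysis of Errorless and Trial-and-Error Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for graph-based functional network analysis of
    errorless versus trial-and-error learning fMRI designs: color-name
    association stimulus generation and behavioral scoring, light time-series
    preprocessing (initial-volume dropping, zero-phase high-pass filtering,
    spherical ROI extraction), correlation-graph construction with per-subject
    proportional thresholding, degree-based within- and between-network
    connectivity statistics over the default mode and fronto-parietal networks,
    the nonparametric repeated-measures comparison design (Wilcoxon, Friedman
    with Bonferroni-corrected post-hoc pairs, Spearman brain-behavior
    correlation), and a block-covariance synthetic-cohort generator that stands
    in for non-public study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite
Config/testthat/edition: 3
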