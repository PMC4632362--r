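Package: gtvconcord
Title: Multimodality Gross Tumour Volume Delineation Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative comparison of radiotherapy gross tumour volume (GTV)
    delineations across CT, MR, combined CT-MR and FDG-PET imaging. Provides a
    voxel-grid geometric data model for binary structure masks, a six-metric
    3-D contour concordance battery (conformity index, DICE, sensitivity and
    inclusion indices, centre-of-gravity distance, mean distance to
    conformity), contrast-oriented adaptive-threshold PET auto-segmentation
    with phantom-based coefficient calibration, inter-observer and
    inter-modality aggregation, cube-root linear mixed-effects volume models
    with ANOVA and Tukey comparisons of variability, and a fully deterministic
    synthetic multi-observer, multi-modality study generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
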