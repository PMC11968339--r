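Package: LymphPlane
Title: Tumor-Lymph Cross-Plane Projection and Attention-Based Survival
    Classification for Chest CT
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms multi-slice tumor and lymph-node regions of interest
    from chest CT into single two-dimensional training planes that preserve
    in-plane spatial relationships (the tumor-lymph projection plane), with
    tumor-only and zoom-center concatenation controls. Provides CT volume and
    mask input/output with Hounsfield-unit windowing and median denoising,
    breadth-first-search grouping of lymph-node voxels into anatomical node
    masses, a residual convolutional classifier with a convolutional block
    attention module trained on binary survival labels, feature-score machine
    learning baselines, survival evaluation (confusion metrics, ROC/AUC,
    Kaplan-Meier curves, log-rank tests), and a synthetic phantom cohort
    generator in which survival hazard is coupled to tumor-lymph spatial
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    survival,
    e1071,
    class,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Survival, Segmentation, Visualization
RoxygenNote: 7.3.3
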