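Package: fedsegbench
Title: Federated Learning Benchmarks for Multi-Site 3D Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Desk-scale benchmarking of federated averaging (FedAvg) against
    local, ensemble and specialized segmentation models on synthetic
    multi-site 3D chest phantoms. Provides a multi-site phantom generator
    with controllable inter-site heterogeneity (voxel spacing, intensity
    shifts, class prevalence, annotation fragmentation), dataset-fingerprint
    synchronization for identical model configuration across sites, a small
    3D encoder-decoder segmentation learner, in-process federated training
    with checkpoint/resume, softmax-probability ensembling and
    specialization, a four-metric segmentation evaluation (Dice, Normalized
    Surface Dice, Hausdorff surface distance, normalized volume error) with
    explicit false-negative penalties and false-positive exclusion, and rank
    aggregation across sites and metrics over personalization and
    generalization scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
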