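Package: radscore
Title: MRI Radiomics and Kernel SVM Risk Scoring for Tumor Progression
Version: 1.0.0
Authors@R:
    person("Radscore", "Developers", email = "radscore@example.org",
           role = c("aut", "cre"))
Description: A reproducible pre-operative MRI radiomics pipeline for
    predicting progression/recurrence of brain tumors from two co-registered
    modalities (contrast-enhanced T1-weighted and T2-weighted volumes).
    Provides a synthetic phantom cohort generator (textured lesions with
    planted class effects, clinical covariates, and exponential-hazard
    time-to-event outcomes), fuzzy c-means lesion segmentation with 3D
    post-processing and affine mask mapping, extraction of 107 radiomic
    features per modality (shape, first-order intensity, GLCM, GLRLM, GLSZM,
    NGTDM, GLDM), Gaussian-kernel support vector machine scoring with
    sequential forward feature selection under repeated stratified
    cross-validation, and downstream evaluation: ROC analysis with Youden
    cutoffs, Kaplan-Meier/log-rank and Cox proportional-hazards survival
    analysis, group-comparison tables, and intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    survival,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
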