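Package: radpanel
Title: Texture-Based Radiomic Marker Screening and Logistic Panel
    Selection for Cystic Lesion Grading
Version: 0.1.0
Authors@R:
    person("radpanel", "maintainers", email = "radpanel@example.org",
           role = c("aut", "cre"))
Description: Quantitative-imaging pipeline for grading cystic pancreatic
    lesions from CT-like volumes. Extracts gray-level co-occurrence matrix
    (GLCM) and first-order texture features from ROI-masked 3D images,
    screens markers by ROC criteria (Mann-Whitney AUC, TPR at fixed FPR,
    Youden index) with Benjamini-Hochberg false-discovery-rate control and
    bootstrap inference, builds logistic marker panels by exhaustive AIC
    search, validates them with two leave-one-third-out cross-validation
    schemes and refit-per-draw bootstrap, visualises cohorts by PCA, and
    classifies lesions by the Fukuoka consensus worrisome features. A
    seeded synthetic-cohort generator (Gaussian random-field textures,
    binormal markers, margin-exact clinical records) makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
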