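Package: radiogenomix
Title: Integrated CT Radiomics and Transcriptomics Modelling for Head and
    Neck Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end radiogenomics workflow for locally advanced head
    and neck squamous cell carcinoma: IBSI-style radiomics feature
    extraction from planning CT (resampling, Hounsfield-unit
    re-segmentation, Laplacian-of-Gaussian filtering; statistical,
    morphological, histogram and texture families), augmentation-based
    feature stability filtering via the intraclass correlation
    coefficient, consensus-cluster-guided reference-batch ComBat
    harmonisation, nearest-centroid molecular subtyping and gene-set
    variation scoring of expression data, MRMR feature selection with
    Borda aggregation under repeated cross-validation, one-versus-all
    logistic and Cox proportional hazards modelling, and the matching
    evaluation statistics (AUC, f1 with reference-value cutoffs,
    concordance, Hosmer-Lemeshow, Greenwood-Nam-d'Agostino calibration,
    log-rank stratification). A seeded synthetic cohort generator
    provides paired image, expression and outcome data with planted,
    recoverable structure for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    survival,
    sva
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
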