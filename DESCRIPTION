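Package: PhantomRadiomics
Title: Phantom-Calibrated Radiomics Modelling of Blood-Rich Liver Lesions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end radiomics pipeline for distinguishing hepatic
    epithelioid angiomyolipoma (HEAML) from hepatocellular carcinoma and
    focal nodular hyperplasia on single-slice contrast-enhanced CT or MRI.
    Provides a calibrated phantom-cohort simulator (lesion images, masks and
    clinical covariate tables), spline resampling and fixed-bin-count
    discretization, a 423-feature panel (7 first-order, 9 GLCM, 13 GLRLM,
    13 GLSZM and 5 NGTDM features on the original image and on 8 stationary
    Haar wavelet channels), mutual-information feature screening, SMOTE
    balancing of the training cohort, grid-searched random forest, ridge
    logistic and neural network signatures, AIC-selected logistic fusion
    models with clinical covariates, and ROC/calibration/decision-curve/
    nomogram evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    RNifti,
    png,
    randomForest,
    glmnet,
    nnet,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
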