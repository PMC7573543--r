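#' Assemble and validate a pipeline configuration
#'
#' A flat, JSON-serializable list of every knob in the pipeline, with the
#' modality-specific study defaults. All seeds are explicit.
#'
#' @param modality "CT" or "MRI".
#' @param ... overrides of the default fields (unknown fields are an error).
#' @return Validated config list.
#' @examples
#' cfg <- pipelineConfig("CT", imageSize = 32L, seed = 3L)
#' @export
pipelineConfig <- function(modality = c("CT", "MRI"), ...) {
    modality <- match.arg(modality)
    cfg <- list(
        modality = modality,
        nPerClass = as.list(cohortSpec(modality)@nPerClass),
        imageSize = 64L,
        pixelSpacing = 1.0,
        texture = "separable",
        format = "nifti",
        nBins = 64L,
        targetSpacing = NULL,
        screeningK = if (modality == "CT") 80L else 95L,
        smoteK = 5L,
        splitRatio = c(2, 1),
        algorithms = c("RF", "RR", "ANN"),
        fusionFolds = 10L,
        rfParams = list(ntree = 300L, nodesize = 1L),
        seed = 1L
    )
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("config schema violation: unknown field ",
                          paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over, keep.null = TRUE)
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname pipelineConfig
#' @param config a config list to validate.
#' @export
validatePipelineConfig <- function(config) {
    if (!config$modality %in% c("CT", "MRI"))
        stop("config schema violation: field 'modality' must be CT or MRI")
    if (config$pixelSpacing <= 0)
        stop("config schema violation: field 'pixelSpacing' must be > 0")
    if (config$imageSize < 16L)
        stop("config schema violation: field 'imageSize' must be >= 16")
    if (config$nBins < 2L)
        stop("config schema violation: field 'nBins' must be >= 2")
    if (any(unlist(config$nPerClass) < 0))
        stop("config schema violation: field 'nPerClass' must be >= 0")
    if (is.null(config$seed))
        stop("config schema violation: field 'seed' is required")
    invisible(TRUE)
}

.cfgSpec <- function(config) {
    cohortSpec(config$modality,
               nPerClass = unlist(config$nPerClass),
               imageSize = config$imageSize,
               pixelSpacing = config$pixelSpacing,
               seed = config$seed)
}

.stageLog <- function(stage, config, inputs = character()) {
    h <- if (length(inputs)) paste(substr(unname(tools::md5sum(inputs)), 1, 8),
                                   collapse = ",") else "-"
    message(sprintf("[%s] seed=%d inputs=%s", stage, config$seed, h))
}

#' Pipeline stages
#'
#' @description
#' \code{runSimulate} writes the phantom dataset; \code{runExtract} the
#' 423-column feature table; \code{runTrain} the screened/balanced cohorts
#' and the three grid-searched signatures with their ROC results;
#' \code{runReport} the fusion cross-validation, decision curves,
#' calibration, nomogram and clinical statistics; \code{runAll} chains the
#' four. Every stage writes flat files plus a JSON manifest so it can be
#' rerun in isolation.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir pipeline output directory.
#' @return Each stage invisibly returns its main in-memory product.
#' @export
runSimulate <- function(config, outDir) {
    validatePipelineConfig(config)
    .stageLog("simulate", config)
    dataDir <- file.path(outDir, "data")
    profiles <- defaultProfiles(config$modality, texture = config$texture)
    manifest <- generateStudy(.cfgSpec(config), profiles, dataDir,
                              format = config$format)
    jsonlite::write_json(config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(manifest)
}

#' @rdname runSimulate
#' @export
runExtract <- function(config, outDir) {
    validatePipelineConfig(config)
    dataDir <- file.path(outDir, "data")
    if (!file.exists(file.path(dataDir, "manifest.json")))
        stop("missing upstream artifact: run the simulate stage first")
    .stageLog("extract", config, file.path(dataDir, "manifest.json"))
    rset <- extractFeatures(dataDir, nBins = config$nBins,
                            targetSpacing = config$targetSpacing)
    tab <- data.frame(subjectId = colnames(rset), featureMatrix(rset),
                      check.names = FALSE)
    write.csv(tab, file.path(outDir, "features.csv"), row.names = FALSE)
    write.csv(featureDictionary(), file.path(outDir, "feature_dictionary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
        list(stage = "extract", seed = config$seed, nBins = config$nBins,
             nSubjects = ncol(rset), nFeatures = nrow(rset)),
        file.path(outDir, "extract_manifest.json"), auto_unbox = TRUE,
        digits = NA)
    invisible(rset)
}

.loadFeatureTable <- function(config, outDir) {
    f <- file.path(outDir, "features.csv")
    if (!file.exists(f))
        stop("missing upstream artifact: run the extract stage first")
    tab <- read.csv(f, check.names = FALSE)
    clinical <- read.csv(file.path(outDir, "data", "clinical.csv"),
                         stringsAsFactors = FALSE)
    rownames(clinical) <- clinical$subjectId
    X <- as.matrix(tab[, -1, drop = FALSE])
    rownames(X) <- tab$subjectId
    radiomicsSet(X, clinical[tab$subjectId, , drop = FALSE],
                 modality = config$modality)
}

#' @rdname runSimulate
#' @export
runTrain <- function(config, outDir) {
    validatePipelineConfig(config)
    .stageLog("train", config, file.path(outDir, "features.csv"))
    rset <- .loadFeatureTable(config, outDir)
    split <- stratifiedSplit(rset, ratio = config$splitRatio, seed = config$seed)
    train <- rset[, trainIds(split)]
    test <- rset[, testIds(split)]
    ranking <- mutualInformationRank(train)
    k <- min(config$screeningK, nrow(ranking))
    write.csv(ranking, file.path(outDir, "screening.csv"), row.names = FALSE)
    trainK <- selectTopK(train, ranking, k)
    testK <- selectTopK(test, ranking, k)
    balanced <- smoteBalance(trainK, kNeighbors = config$smoteK,
                             seed = config$seed)
    models <- list()
    perf <- list()
    for (alg in config$algorithms) {
        m <- gridSearchFit(alg, balanced, seed = config$seed)
        models[[alg]] <- m
        perf[[alg]] <- list(
            selected = m@selected$point,
            internalCvAuc = m@selected$cvAuc,
            trainAuc = auc(rocAuc(predictScores(m, trainK), groupLabels(trainK))),
            testAuc = auc(rocAuc(predictScores(m, testK), groupLabels(testK)))
        )
    }
    jsonlite::write_json(
        list(stage = "train", seed = config$seed, k = k,
             split = list(train = trainIds(split), test = testIds(split)),
             performance = perf),
        file.path(outDir, "train_manifest.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    out <- list(models = models, split = split, ranking = ranking,
                performance = perf)
    invisible(out)
}

#' @rdname runSimulate
#' @param plots write base-graphics PNG figures of the ROC and decision
#'   curves (default TRUE).
#' @export
runReport <- function(config, outDir, plots = TRUE) {
    validatePipelineConfig(config)
    .stageLog("report", config, file.path(outDir, "features.csv"))
    rset <- .loadFeatureTable(config, outDir)
    cvF <- crossValidateFusion(rset, k = config$screeningK,
                               folds = config$fusionFolds, seed = config$seed,
                               mode = "fusion", rfParams = config$rfParams)
    cvS <- crossValidateFusion(rset, k = config$screeningK,
                               folds = config$fusionFolds, seed = config$seed,
                               mode = "signature", rfParams = config$rfParams)
    cvC <- crossValidateFusion(rset, k = config$screeningK,
                               folds = config$fusionFolds, seed = config$seed,
                               mode = "clinical", rfParams = config$rfParams)
    y <- groupLabels(rset)
    dca <- decisionCurve(cvF$predictions, y)
    write.csv(dca, file.path(outDir, "decision_curve.csv"), row.names = FALSE)
    calib <- calibrationCurve(cvF$predictions, y,
                              nGroups = min(10L, length(y)))
    write.csv(calib, file.path(outDir, "calibration.csv"), row.names = FALSE)
    stats <- clinicalStats(clinicalData(rset))
    write.csv(stats, file.path(outDir, "clinical_stats.csv"), row.names = FALSE)
    # final fusion model on the full cohort (out-of-fold signature scores)
    ranking <- mutualInformationRank(rset)
    kf <- min(config$screeningK, nrow(ranking))
    rsetK <- selectTopK(rset, ranking, kf)
    oof <- crossValidateFusion(rsetK, k = kf, folds = 5L, seed = config$seed,
                               mode = "signature",
                               rfParams = config$rfParams)$predictions
    prep <- prepFusionData(clinicalData(rset), score = oof)
    fusion <- aicSelect(prep$data, scoreCol = "score")
    nom <- buildNomogram(fusion)
    jsonlite::write_json(
        list(covariates = fusion@covariates,
             coefficients = as.list(coef(fusion)), aic = aicValue(fusion),
             nomogram = list(offset = nom@offset, maxRange = nom@maxRange,
                             scales = nom@scales)),
        file.path(outDir, "fusion_model.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    metrics <- list(
        stage = "report", seed = config$seed,
        fusion = list(foldAuc = cvF$foldAuc, meanAuc = cvF$meanAuc,
                      pooledAuc = cvF$pooledAuc),
        signature = list(meanAuc = cvS$meanAuc, pooledAuc = cvS$pooledAuc),
        clinical = list(meanAuc = cvC$meanAuc, pooledAuc = cvC$pooledAuc)
    )
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (plots) {
        grDevices::png(file.path(outDir, "report_curves.png"),
                       width = 900, height = 450)
        op <- graphics::par(mfrow = c(1, 2))
        roc <- rocAuc(cvF$predictions, y)
        graphics::plot(rocCurve(roc)$fpr, rocCurve(roc)$tpr, type = "l",
                       xlab = "1 - specificity", ylab = "sensitivity",
                       main = sprintf("Fusion CV ROC (AUC %.3f)", auc(roc)))
        graphics::abline(0, 1, lty = 3)
        graphics::plot(dca$threshold, dca$model, type = "l", ylim = c(-0.1, 0.5),
                       xlab = "threshold probability", ylab = "net benefit",
                       main = "Decision curves")
        graphics::lines(dca$threshold, dca$all, lty = 2)
        graphics::abline(h = 0, lty = 3)
        graphics::par(op)
        grDevices::dev.off()
    }
    invisible(metrics)
}

#' @rdname runSimulate
#' @export
runAll <- function(config, outDir, plots = TRUE) {
    runSimulate(config, outDir)
    runExtract(config, outDir)
    runTrain(config, outDir)
    runReport(config, outDir, plots = plots)
}
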