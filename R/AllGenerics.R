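#' @name accessors
#' @title Accessors for PhantomRadiomics classes
#' @description Slot accessors for the core S4 containers.
#' @param object,x an object of the documented class.
#' @param ... unused.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "PhantomCase", function(object) object@image)

#' @rdname accessors
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setMethod("maskData", "PhantomCase", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PhantomCase", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("modalityTag", function(object) standardGeneric("modalityTag"))
#' @rdname accessors
#' @export
setMethod("modalityTag", "PhantomCase", function(object) object@modality)
#' @rdname accessors
#' @export
setMethod("modalityTag", "RadiomicsSet", function(object) metadata(object)$modality)

#' @rdname accessors
#' @export
setGeneric("roiLevels", function(object) standardGeneric("roiLevels"))
#' @rdname accessors
#' @export
setMethod("roiLevels", "DiscretizedRoi", function(object) object@levels)

#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setMethod("nBins", "DiscretizedRoi", function(object) object@nBins)

#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setMethod("channelName", "DiscretizedRoi", function(object) object@channel)

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' Subjects-in-rows feature matrix of a RadiomicsSet
#' @rdname accessors
#' @export
setMethod("featureMatrix", "RadiomicsSet", function(object) t(assay(object, "features")))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' Binary labels, 1 = HEAML, 0 = non-HEAML
#' @rdname accessors
#' @export
setMethod("groupLabels", "RadiomicsSet", function(object) {
    setNames(as.integer(colData(object)$group == "HEAML"), colnames(object))
})

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))
#' @rdname accessors
#' @export
setMethod("clinicalData", "RadiomicsSet", function(object) {
    as.data.frame(colData(object))
})

#' @rdname accessors
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))
#' @rdname accessors
#' @export
setMethod("trainIds", "CohortSplit", function(object) object@trainIds)

#' @rdname accessors
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))
#' @rdname accessors
#' @export
setMethod("testIds", "CohortSplit", function(object) object@testIds)

#' @rdname accessors
#' @export
setGeneric("algorithmName", function(object) standardGeneric("algorithmName"))
#' @rdname accessors
#' @export
setMethod("algorithmName", "SignatureModel", function(object) object@algorithm)

#' @rdname accessors
#' @export
setGeneric("selectedHyperparameters",
    function(object) standardGeneric("selectedHyperparameters"))
#' @rdname accessors
#' @export
setMethod("selectedHyperparameters", "SignatureModel",
    function(object) object@selected$point)

#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setMethod("auc", "RocResult", function(object) object@auc)

#' @rdname accessors
#' @export
setGeneric("aucCI", function(object) standardGeneric("aucCI"))
#' @rdname accessors
#' @export
setMethod("aucCI", "RocResult", function(object) object@ci)

#' @rdname accessors
#' @export
setGeneric("rocCurve", function(object) standardGeneric("rocCurve"))
#' @rdname accessors
#' @export
setMethod("rocCurve", "RocResult", function(object) object@curve)

#' @rdname accessors
#' @export
setGeneric("aicValue", function(object) standardGeneric("aicValue"))
#' @rdname accessors
#' @export
setMethod("aicValue", "FusionModel", function(object) object@aic)

#' @rdname accessors
#' @export
setGeneric("fusionCovariates", function(object) standardGeneric("fusionCovariates"))
#' @rdname accessors
#' @export
setMethod("fusionCovariates", "FusionModel", function(object) object@covariates)

#' @rdname accessors
#' @export
setMethod("coef", "FusionModel", function(object, ...) object@coefficients)

setMethod("show", "ClassProfile", function(object) {
    cat("ClassProfile:", object@classLabel, "\n",
        sprintf("  female %.2f | age %.1f +/- %.1f y | diameter %.1f +/- %.1f cm\n",
            object@femaleProb, object@ageMean, object@ageSd,
            object@diamMean, object@diamSd),
        sprintf("  left lobe %.2f | alcoholism/smoking %.2f\n",
            object@leftLobeProb, object@habitProb),
        sprintf("  texture: base %.0f, noise %.1f, corr.len %.1f px, amp %.1f\n",
            object@texture$baseIntensity, object@texture$noiseSd,
            object@texture$correlationLength, object@texture$heterogeneityAmp),
        sep = "")
})

setMethod("show", "PhantomCase", function(object) {
    cat(sprintf("PhantomCase (%s): %d x %d px, spacing %.3g x %.3g mm, %d ROI px\n",
        object@modality, nrow(object@image), ncol(object@image),
        object@spacing[1], object@spacing[2], sum(object@mask)))
})

setMethod("show", "DiscretizedRoi", function(object) {
    cat(sprintf("DiscretizedRoi [%s]: %d x %d px, %d bins, %d ROI px\n",
        object@channel, nrow(object@levels), ncol(object@levels),
        object@nBins, sum(object@levels != 0L)))
})

setMethod("show", "CohortSplit", function(object) {
    cat(sprintf("CohortSplit: %d train / %d test (seed %d)\n",
        length(object@trainIds), length(object@testIds), object@seed))
})

setMethod("show", "SignatureModel", function(object) {
    cat(sprintf("SignatureModel [%s]: %d features, internal CV AUC %.3f\n",
        object@algorithm, length(object@featureNames),
        object@selected$cvAuc))
    cat("  selected:", paste(names(object@selected$point),
        unlist(object@selected$point), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC %.3f (95%% CI %.3f-%.3f, DeLong)\n",
        object@auc, object@ci[1], object@ci[2]))
})

setMethod("show", "FusionModel", function(object) {
    cat(sprintf("FusionModel: AIC %.2f, logLik %.3f%s\n", object@aic,
        object@logLik, if (object@separation) " [ridge-stabilized]" else ""))
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

setMethod("show", "Nomogram", function(object) {
    cat(sprintf("Nomogram: %d scales, max contribution range %.3f\n",
        length(object@scales), object@maxRange))
})
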