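#' Class profile: clinical and texture parameters of one lesion class
#'
#' A \code{ClassProfile} holds the class-conditional generative parameters of
#' the phantom cohort simulator: the Bernoulli probabilities and Gaussian
#' moments of the clinical covariates, and the lesion texture parameters
#' (base intensity, white-noise SD, correlation length of the smoothed
#' Gaussian heterogeneity field, and its amplitude).
#'
#' @slot classLabel one of \code{"HEAML"}, \code{"HCC"}, \code{"FNH"}.
#' @slot femaleProb probability that a subject is female.
#' @slot ageMean,ageSd age distribution in years (Gaussian, truncated at 0).
#' @slot diamMean,diamSd maximum lesion diameter in cm (Gaussian, truncated
#'   at 0).
#' @slot leftLobeProb probability the lesion sits in the left lobe.
#' @slot habitProb probability of alcoholism or smoking.
#' @slot texture named list with elements \code{baseIntensity},
#'   \code{noiseSd}, \code{correlationLength} (pixels, >= 1) and
#'   \code{heterogeneityAmp}.
#' @seealso [classProfile()], [defaultProfiles()]
#' @export
setClass("ClassProfile",
    representation(
        classLabel = "character",
        femaleProb = "numeric",
        ageMean = "numeric", ageSd = "numeric",
        diamMean = "numeric", diamSd = "numeric",
        leftLobeProb = "numeric",
        habitProb = "numeric",
        texture = "list"
    )
)

setValidity("ClassProfile", function(object) {
    msg <- character()
    probs <- c(object@femaleProb, object@leftLobeProb, object@habitProb)
    if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    if (object@ageSd < 0 || object@diamSd < 0) msg <- c(msg, "sd must be >= 0")
    if (object@diamMean <= 0) msg <- c(msg, "diamMean must be > 0")
    need <- c("baseIntensity", "noiseSd", "correlationLength", "heterogeneityAmp")
    if (!all(need %in% names(object@texture)))
        msg <- c(msg, paste("texture must name", paste(need, collapse = ", ")))
    else {
        if (object@texture$correlationLength < 1)
            msg <- c(msg, "texture$correlationLength must be >= 1")
        if (object@texture$noiseSd < 0 || object@texture$heterogeneityAmp < 0)
            msg <- c(msg, "texture noiseSd and heterogeneityAmp must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Cohort specification for the phantom simulator
#'
#' @slot modality \code{"CT"} or \code{"MRI"}; selects which printed cohort
#'   the default class sizes and profiles mirror.
#' @slot nPerClass named integer vector of subjects per class.
#' @slot imageSize side of the square phantom image in pixels (>= 16).
#' @slot pixelSpacing in-plane pixel spacing in mm.
#' @slot seed master seed; every generator output is a pure function of
#'   (spec, profiles, seed).
#' @seealso [cohortSpec()]
#' @export
setClass("CohortSpec",
    representation(
        modality = "character",
        nPerClass = "integer",
        imageSize = "integer",
        pixelSpacing = "numeric",
        seed = "integer"
    )
)

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (!object@modality %in% c("CT", "MRI")) msg <- c(msg, "modality must be CT or MRI")
    if (any(object@nPerClass < 0)) msg <- c(msg, "nPerClass must be >= 0")
    if (is.null(names(object@nPerClass)) || any(!nzchar(names(object@nPerClass))))
        msg <- c(msg, "nPerClass must be named by class label")
    if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
    if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
    if (length(msg)) msg else TRUE
})

#' A 2-D lesion image with its aligned binary ROI mask
#'
#' @slot image numeric matrix of gray values (finite).
#' @slot mask integer matrix of the same shape, 1 inside the lesion ROI and
#'   0 outside.
#' @slot spacing numeric length-2 (row mm, column mm), both > 0.
#' @slot modality modality tag carried through the pipeline.
#' @seealso [phantomCase()], [generatePhantom()], [loadCase()]
#' @export
setClass("PhantomCase",
    representation(
        image = "matrix",
        mask = "matrix",
        spacing = "numeric",
        modality = "character"
    )
)

setValidity("PhantomCase", function(object) {
    msg <- character()
    if (!all(dim(object@image) == dim(object@mask)))
        msg <- c(msg, "image and mask must share dimensions")
    if (!all(is.finite(object@image))) msg <- c(msg, "image values must be finite")
    if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary 0/1")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be two positive values (mm)")
    if (length(msg)) msg else TRUE
})

#' A mask-restricted image discretized to a fixed number of gray levels
#'
#' Values are 0 outside the mask and in 1..\code{nBins} inside.
#'
#' @slot levels integer matrix.
#' @slot nBins number of gray levels used for the in-mask binning.
#' @slot channel provenance tag (e.g. \code{"original"}, \code{"L1.HH"}).
#' @seealso [discretizeRoi()]
#' @export
setClass("DiscretizedRoi",
    representation(levels = "matrix", nBins = "integer", channel = "character")
)

setValidity("DiscretizedRoi", function(object) {
    msg <- character()
    v <- object@levels
    inmask <- v[v != 0L]
    if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
    if (length(inmask) && (min(inmask) < 1L || max(inmask) > object@nBins))
        msg <- c(msg, "in-mask levels must lie in 1..nBins")
    if (any(v < 0L)) msg <- c(msg, "levels must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Subjects-by-features container for the radiomics pipeline
#'
#' \code{RadiomicsSet} extends \linkS4class{SummarizedExperiment}: the
#' \code{"features"} assay holds the feature matrix (features in rows,
#' subjects in columns) and \code{colData} carries the clinical covariates,
#' the three-way class label, the binary \code{group} (HEAML vs non-HEAML)
#' and a \code{synthetic} flag for SMOTE rows.
#'
#' @seealso [radiomicsSet()], [extractFeatures()], [smoteBalance()]
#' @export
setClass("RadiomicsSet", contains = "SummarizedExperiment")

setValidity("RadiomicsSet", function(object) {
    msg <- character()
    if (!"features" %in% assayNames(object)) msg <- c(msg, "assay 'features' required")
    cd <- colData(object)
    if (!all(c("group", "synthetic") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'group' and 'synthetic'")
    else if (!all(cd$group %in% c("HEAML", "nonHEAML")))
        msg <- c(msg, "group must be HEAML or nonHEAML")
    if ("features" %in% assayNames(object) &&
        anyNA(assay(object, "features")))
        msg <- c(msg, "feature matrix must have no missing values")
    if (length(msg)) msg else TRUE
})

#' Train/test partition of a cohort
#'
#' @slot trainIds,testIds disjoint subject-id sets whose union covers the
#'   cohort; within each class the test share is floor(n/3) (2:1 split).
#' @slot seed seed used for the random assignment.
#' @seealso [stratifiedSplit()]
#' @export
setClass("CohortSplit",
    representation(trainIds = "character", testIds = "character", seed = "integer")
)

setValidity("CohortSplit", function(object) {
    if (length(intersect(object@trainIds, object@testIds)))
        "train and test ids must be disjoint" else TRUE
})

#' A fitted radiomics signature model
#'
#' @slot algorithm \code{"RF"} (random forest), \code{"RR"} (ridge logistic
#'   regression) or \code{"ANN"} (single-hidden-layer neural network).
#' @slot fit the underlying fitted object.
#' @slot grid declared hyperparameter grid (one row per point).
#' @slot selected selected grid point (named list) and its internal CV AUC.
#' @slot featureNames training feature columns, order-free contract for
#'   prediction.
#' @slot center,scale training standardization used for RR/ANN.
#' @slot manifest training manifest (seed, cohort sizes, algorithm settings).
#' @seealso [gridSearchFit()], [predictScores()]
#' @export
setClass("SignatureModel",
    representation(
        algorithm = "character",
        fit = "ANY",
        grid = "data.frame",
        selected = "list",
        featureNames = "character",
        center = "numeric",
        scale = "numeric",
        manifest = "list"
    )
)

#' ROC summary with DeLong confidence interval
#'
#' @slot auc area under the ROC curve (tie-aware pairwise concordance).
#' @slot ci 95\% DeLong confidence interval, truncated to [0, 1].
#' @slot curve data.frame with \code{fpr}, \code{tpr}, \code{threshold}.
#' @seealso [rocAuc()]
#' @export
setClass("RocResult",
    representation(auc = "numeric", ci = "numeric", curve = "data.frame")
)

setValidity("RocResult", function(object) {
    msg <- character()
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
    if (length(object@ci) != 2L) msg <- c(msg, "ci must be length 2")
    else if (object@ci[1] > object@auc + 1e-12 || object@ci[2] < object@auc - 1e-12)
        msg <- c(msg, "ci must contain the AUC")
    if (length(msg)) msg else TRUE
})

#' AIC-selected logistic fusion model
#'
#' Combines the radiomics signature score with the clinical covariate subset
#' minimizing the AIC (signature score always included).
#'
#' @slot covariates covariate names in the linear predictor (signature score
#'   first).
#' @slot coefficients named coefficients including \code{(Intercept)}.
#' @slot logLik maximized log-likelihood.
#' @slot aic 2 * n_parameters - 2 * logLik.
#' @slot separation TRUE when perfect separation was detected and the fit was
#'   ridge-stabilized (penalty 1e-6).
#' @slot ranges 2 x p matrix (min/max of each covariate over the fitting
#'   data), consumed by [buildNomogram()].
#' @seealso [fitLogistic()], [aicSelect()]
#' @export
setClass("FusionModel",
    representation(
        covariates = "character",
        coefficients = "numeric",
        logLik = "numeric",
        aic = "numeric",
        separation = "logical",
        ranges = "matrix"
    )
)

setValidity("FusionModel", function(object) {
    k <- length(object@coefficients)
    if (abs(object@aic - (2 * k - 2 * object@logLik)) > 1e-6)
        "aic must equal 2k - 2 logLik" else TRUE
})

#' Points-scale nomogram of a logistic fusion model
#'
#' Each covariate contribution beta * x is mapped affinely to points, with
#' the widest-ranging covariate spanning 0-100; total points map back to the
#' predicted probability through the logistic inverse of the reassembled
#' linear predictor.
#'
#' @slot scales per-covariate list: \code{beta}, \code{ref} (range endpoint
#'   minimizing beta * x), \code{points} at the two range endpoints.
#' @slot maxRange widest covariate contribution range |beta| * (max - min).
#' @slot offset intercept plus sum of beta * ref over covariates.
#' @seealso [buildNomogram()], [nomogramProbability()]
#' @export
setClass("Nomogram",
    representation(scales = "list", maxRange = "numeric", offset = "numeric")
)
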