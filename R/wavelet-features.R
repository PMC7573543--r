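# shift rows down by d with symmetric (reflect) border extension
.shiftRefl <- function(mat, d) {
    n <- nrow(mat)
    src <- seq_len(n) + d
    src <- ifelse(src > n, 2L * n - src, src)
    src <- ifelse(src < 1L, 2L - src, src)
    mat[src, , drop = FALSE]
}

#' Stationary Haar wavelet channels
#'
#' Two-level undecimated (a trous) Haar decomposition with symmetric border
#' extension. At dilation d the row/column analysis pair is
#' A = (x + S_d x) / 2 and D = (x - S_d x) / 2, so every sub-band stays at
#' the original image size and the lone inverse reconstruction of a sub-band
#' equals its coefficient image. Level 1 uses d = 1 on the input; level 2
#' uses d = 2 on the level-1 LL band. The four level-1 channels sum exactly
#' to the input and the four level-2 channels to L1.LL.
#'
#' @param image numeric matrix (at least 4 x 4) or a
#'   \linkS4class{PhantomCase}.
#' @return Named list of 8 matrices: L1.LL, L1.LH, L1.HL, L1.HH, L2.LL,
#'   L2.LH, L2.HL, L2.HH (first letter = row filter, second = column
#'   filter).
#' @examples
#' ch <- haarChannels(matrix(rnorm(64), 8, 8))
#' names(ch)
#' @export
haarChannels <- function(image) {
    if (is(image, "PhantomCase")) image <- image@image
    if (nrow(image) < 4L || ncol(image) < 4L)
        stop("image too small for a two-level wavelet decomposition (need >= 4x4)")
    decompose <- function(x, d) {
        rowA <- (x + .shiftRefl(x, d)) / 2
        rowD <- (x - .shiftRefl(x, d)) / 2
        colOp <- function(m, detail) {
            t(if (detail) (t(m) - .shiftRefl(t(m), d)) / 2
          else (t(m) + .shiftRefl(t(m), d)) / 2)
        }
        list(LL = colOp(rowA, FALSE), LH = colOp(rowA, TRUE),
             HL = colOp(rowD, FALSE), HH = colOp(rowD, TRUE))
    }
    l1 <- decompose(image, 1L)
    l2 <- decompose(l1$LL, 2L)
    setNames(c(l1, l2),
             c("L1.LL", "L1.LH", "L1.HL", "L1.HH",
               "L2.LL", "L2.LH", "L2.HL", "L2.HH"))
}

#' The 376 wavelet features of a case
#'
#' Each of the 8 wavelet channels is discretized within the ROI mask (same
#' fixed-bin-count rule as the original image) and passed through the
#' 47-feature panel, giving 8 x 47 = 376 namespaced features.
#'
#' @param channels list from [haarChannels()].
#' @param mask binary ROI mask aligned with the channels.
#' @param nBins gray levels for the per-channel discretization.
#' @return Named numeric vector of length 376.
#' @export
waveletFeatureSet <- function(channels, mask, nBins = 64L) {
    stopifnot(length(channels) == 8L)
    out <- unlist(lapply(names(channels), function(nm) {
        roi <- discretizeRoi(channels[[nm]], mask, nBins = nBins, channel = nm)
        channelFeatureSet(roi)
    }))
    stopifnot(length(out) == 376L)
    out
}

#' The full 423-feature vector of a preprocessed case
#'
#' 47 original-channel features plus 376 wavelet features, in a stable,
#' versioned order matching [featureDictionary()].
#'
#' @param case a resampled \linkS4class{PhantomCase}.
#' @param nBins gray levels for discretization (default 64).
#' @return Named numeric vector of length 423.
#' @export
fullFeatureVector <- function(case, nBins = 64L) {
    validObject(case)
    orig <- channelFeatureSet(discretizeRoi(case@image, case@mask,
                                            nBins = nBins,
                                            channel = "original"))
    wav <- waveletFeatureSet(haarChannels(case@image), case@mask, nBins = nBins)
    v <- c(orig, wav)
    stopifnot(length(v) == 423L, !anyDuplicated(names(v)))
    v
}

#' Dictionary of the 423-feature panel
#'
#' @return data.frame with columns \code{feature}, \code{channel},
#'   \code{family}, \code{statistic}, in the extraction order.
#' @export
featureDictionary <- function() {
    fam <- list(
        firstorder = c("mean", "variance", "skewness", "kurtosis", "energy",
                       "entropy", "uniformity"),
        glcm = c("contrast", "correlation", "energy", "entropy", "homogeneity",
                 "variance", "sum_average", "dissimilarity", "cluster_shade"),
        glrlm = c("sre", "lre", "gln", "rln", "rp", "lglre", "hglre",
                  "srlgle", "srhgle", "lrlgle", "lrhgle", "glv", "rlv"),
        glszm = c("sze", "lze", "gln", "zsn", "zp", "lglze", "hglze",
                  "szlgle", "szhgle", "lzlgle", "lzhgle", "glv", "zsv"),
        ngtdm = c("coarseness", "contrast", "busyness", "complexity",
                  "strength")
    )
    channels <- c("original", "L1.LL", "L1.LH", "L1.HL", "L1.HH",
                  "L2.LL", "L2.LH", "L2.HL", "L2.HH")
    do.call(rbind, lapply(channels, function(ch) {
        do.call(rbind, lapply(names(fam), function(fm) {
            data.frame(feature = paste(ch, fm, fam[[fm]], sep = "."),
                       channel = ch, family = fm, statistic = fam[[fm]],
                       stringsAsFactors = FALSE)
        }))
    }))
}

#' Assemble a RadiomicsSet from a feature matrix and clinical table
#'
#' @param features numeric matrix, subjects in rows, features in columns.
#' @param clinical data.frame with one row per subject (same order),
#'   including \code{group} ("HEAML"/"nonHEAML").
#' @param modality modality tag stored in the metadata.
#' @return A \linkS4class{RadiomicsSet}.
#' @export
radiomicsSet <- function(features, clinical, modality = "CT") {
    stopifnot(nrow(features) == nrow(clinical), "group" %in% colnames(clinical))
    cd <- DataFrame(clinical)
    if (!"synthetic" %in% colnames(cd)) cd$synthetic <- FALSE
    rownames(cd) <- if (!is.null(clinical$subjectId)) clinical$subjectId
                    else rownames(clinical)
    se <- SummarizedExperiment(
        assays = list(features = t(features)),
        colData = cd
    )
    colnames(se) <- rownames(cd)
    out <- new("RadiomicsSet", se)
    metadata(out)$modality <- modality
    validObject(out)
    out
}

#' Extract the 423-feature table of a cohort
#'
#' Runs preprocessing (optional spline resampling to a common spacing,
#' 64-bin discretization) and the full feature panel on every case and
#' returns the subjects-by-features container.
#'
#' @param study a directory written by [generateStudy()], or a list with
#'   elements \code{cases} (named list of \linkS4class{PhantomCase}) and
#'   \code{clinical} (data.frame keyed by subjectId).
#' @param nBins gray levels for discretization.
#' @param targetSpacing if non-NULL, resample each case to this spacing
#'   first.
#' @return A \linkS4class{RadiomicsSet} (423 feature rows x subjects).
#' @export
extractFeatures <- function(study, nBins = 64L, targetSpacing = NULL) {
    if (is.character(study)) study <- loadStudy(study)
    cases <- study$cases
    clinical <- study$clinical
    stopifnot(all(names(cases) %in% clinical$subjectId))
    clinical <- clinical[names(cases), , drop = FALSE]
    feats <- vapply(cases, function(cs) {
        if (!is.null(targetSpacing)) cs <- resampleCase(cs, targetSpacing)
        fullFeatureVector(cs, nBins = nBins)
    }, numeric(423L))
    modality <- if (length(cases)) cases[[1]]@modality else "CT"
    radiomicsSet(t(feats), clinical, modality = modality)
}
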