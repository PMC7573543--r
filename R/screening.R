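#' Stratified 2:1 train/test split
#'
#' Within each group (HEAML, non-HEAML), floor(n * test share) subjects are
#' assigned to the test cohort at random (the remainder to training), so the
#' group composition is consistent across cohorts and train >= test always.
#'
#' @param rset a \linkS4class{RadiomicsSet}.
#' @param ratio length-2 train:test weights; the default 2:1 sends
#'   floor(n/3) of each group to the test cohort.
#' @param seed split seed.
#' @return A \linkS4class{CohortSplit}.
#' @examples
#' # 33 HEAML + 137 non-HEAML -> test gets 11 + 45
#' @export
stratifiedSplit <- function(rset, ratio = c(2, 1), seed = 1L) {
    stopifnot(is(rset, "RadiomicsSet"), length(ratio) == 2L, all(ratio >= 0),
              sum(ratio) > 0)
    grp <- colData(rset)$group
    ids <- colnames(rset)
    testFrac <- ratio[2] / sum(ratio)
    set.seed(as.integer(seed))
    testIds <- unlist(lapply(unique(grp), function(g) {
        gi <- ids[grp == g]
        if (testFrac > 0 && length(gi) < 3L)
            stop("class too small for a stratified split: ", g)
        nTest <- floor(length(gi) * testFrac)
        if (nTest == 0L) character() else sample(gi, nTest)
    }))
    new("CohortSplit", trainIds = setdiff(ids, testIds),
        testIds = as.character(testIds), seed = as.integer(seed))
}

# equal-frequency binning with merged ties; returns integer bin codes
.eqFreqBin <- function(x, nbin = 10L) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nbin + 1L),
                          names = FALSE, type = 7))
    if (length(br) < 2L) return(rep(1L, length(x)))   # constant feature
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# plug-in mutual information (nats) between two discrete codes
.plugInMi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}

#' Mutual-information ranking of the features
#'
#' Each feature is discretized into 10 equal-frequency bins (tied quantiles
#' merged) and the plug-in mutual information with the binary group label is
#' computed in nats. Features are returned in descending MI order, ties
#' broken by feature name, so the ranking is deterministic.
#'
#' @param rset the training-cohort \linkS4class{RadiomicsSet} (screening
#'   never sees test subjects by construction of the interface).
#' @return data.frame(feature, mi, rank).
#' @export
mutualInformationRank <- function(rset) {
    stopifnot(is(rset, "RadiomicsSet"))
    y <- groupLabels(rset)
    if (length(unique(y)) < 2L) stop("constant label: cannot rank features")
    X <- featureMatrix(rset)
    mi <- vapply(colnames(X), function(f) .plugInMi(.eqFreqBin(X[, f]), y),
                 numeric(1))
    ord <- order(-mi, colnames(X))
    data.frame(feature = colnames(X)[ord], mi = unname(mi[ord]),
               rank = seq_along(mi), stringsAsFactors = FALSE)
}

#' Keep the top-k ranked features
#'
#' Defaults follow the printed panel sizes: k = 80 for CT, 95 for MRI.
#'
#' @param rset a \linkS4class{RadiomicsSet}.
#' @param ranking data.frame from [mutualInformationRank()] (computed on the
#'   training cohort).
#' @param k number of features to keep.
#' @return The reduced \linkS4class{RadiomicsSet} (feature rows in ranking
#'   order).
#' @export
selectTopK <- function(rset, ranking, k = NULL) {
    stopifnot(is(rset, "RadiomicsSet"))
    if (is.null(k)) k <- if (identical(modalityTag(rset), "MRI")) 95L else 80L
    if (k < 1L || k > nrow(ranking))
        stop("k out of range: ", k, " (have ", nrow(ranking), " ranked features)")
    rset[ranking$feature[seq_len(k)], ]
}

#' SMOTE balancing of a training cohort
#'
#' Raises the minority group to the majority size: each synthetic sample is
#' x + u * (z - x) with u ~ Uniform(0, 1), where x is a random minority
#' sample and z one of its k nearest minority neighbours (Euclidean distance
#' on train-standardized features; the interpolation itself happens in the
#' original feature space, so every synthetic row is an exact convex
#' combination of two same-class originals). Original rows are preserved and
#' synthetic rows are flagged in \code{colData()$synthetic}.
#'
#' @param rset the training-cohort \linkS4class{RadiomicsSet}.
#' @param kNeighbors neighbourhood size (default 5, capped at minority
#'   size - 1).
#' @param seed RNG seed.
#' @return The balanced \linkS4class{RadiomicsSet}.
#' @export
smoteBalance <- function(rset, kNeighbors = 5L, seed = 1L) {
    stopifnot(is(rset, "RadiomicsSet"))
    y <- groupLabels(rset)
    nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
    if (nPos == nNeg) return(rset)
    minLab <- if (nPos < nNeg) 1L else 0L
    need <- abs(nPos - nNeg)
    minIdx <- which(y == minLab)
    if (length(minIdx) < 2L)
        stop("minority class of size 1: SMOTE needs at least 2 samples")
    X <- featureMatrix(rset)
    Xmin <- X[minIdx, , drop = FALSE]
    ctr <- colMeans(Xmin)
    scl <- apply(Xmin, 2, sd)
    scl[scl == 0] <- 1
    Z <- sweep(sweep(Xmin, 2, ctr), 2, scl, "/")
    D <- as.matrix(dist(Z))
    diag(D) <- Inf
    k <- min(kNeighbors, nrow(Xmin) - 1L)
    nbr <- apply(D, 1, function(r) order(r)[seq_len(k)])
    nbr <- if (k == 1L) matrix(nbr, ncol = 1L) else t(nbr)
    set.seed(as.integer(seed))
    base <- sample(nrow(Xmin), need, replace = TRUE)
    pick <- sample(k, need, replace = TRUE)
    u <- runif(need)
    syn <- Xmin[base, , drop = FALSE] +
        u * (Xmin[nbr[cbind(base, pick)], , drop = FALSE] -
             Xmin[base, , drop = FALSE])
    rownames(syn) <- sprintf("SYN_%03d", seq_len(need))
    clin <- clinicalData(rset)
    synClin <- clin[minIdx[base], , drop = FALSE]
    if ("subjectId" %in% colnames(synClin)) synClin$subjectId <- rownames(syn)
    synClin$synthetic <- TRUE
    rownames(synClin) <- rownames(syn)
    allClin <- rbind(clin, synClin)
    allClin$subjectId <- rownames(allClin)
    out <- radiomicsSet(rbind(X, syn), allClin, modality = modalityTag(rset))
    metadata(out)$smote <- list(kNeighbors = k, seed = as.integer(seed),
                                nSynthetic = need)
    out
}
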