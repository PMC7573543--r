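#' Declared hyperparameter grids of the signature algorithms
#'
#' Package defaults: random forest over trees x node size, ridge logistic
#' regression over penalties 1e-3..1e3 by decade, neural network over hidden
#' units x weight decay. Grids are plain data.frames (one row per point) and
#' can be replaced wholesale.
#'
#' @param algorithm "RF", "RR" or "ANN".
#' @return data.frame grid in the declared tie-break order.
#' @export
signatureGrid <- function(algorithm = c("RF", "RR", "ANN")) {
    switch(match.arg(algorithm),
        RF = expand.grid(ntree = c(100L, 300L, 500L),
                         nodesize = c(1L, 5L, 10L)),
        RR = data.frame(lambda = 10^seq(-3, 3)),
        ANN = expand.grid(size = c(4L, 16L), decay = c(1e-4, 1e-2)))
}

# stratified fold assignment; every fold holds both classes when each class
# has >= nFolds members
.stratFolds <- function(y, nFolds, seed) {
    set.seed(as.integer(seed))
    fold <- integer(length(y))
    for (g in unique(y)) {
        idx <- sample(which(y == g))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    fold
}

# tie-aware pairwise concordance (rank formula)
.aucValue <- function(scores, labels) {
    nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
    stopifnot(nPos > 0L, nNeg > 0L)
    r <- rank(scores)
    (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.standardize <- function(X, ctr, scl) sweep(sweep(X, 2, ctr), 2, scl, "/")

# fit one algorithm at one grid point; X is the raw feature matrix
.fitPoint <- function(algorithm, X, y, point, ctr, scl, seed) {
    set.seed(as.integer(seed))
    if (algorithm == "RF") {
        randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                                   ntree = point$ntree,
                                   nodesize = point$nodesize)
    } else if (algorithm == "RR") {
        # suppress glmnet's small-class advisory: internal CV folds are small
        # by design and the caller controls the class sizes
        suppressWarnings(
            glmnet::glmnet(.standardize(X, ctr, scl), y, family = "binomial",
                           alpha = 0, lambda = point$lambda,
                           standardize = FALSE))
    } else {
        nnet::nnet(.standardize(X, ctr, scl), y, size = point$size,
                   decay = point$decay, maxit = 300L, MaxNWts = 100000L,
                   entropy = TRUE, trace = FALSE)
    }
}

.scorePoint <- function(algorithm, fit, X, point, ctr, scl) {
    if (algorithm == "RF") {
        unname(predict(fit, X, type = "prob")[, "1"])
    } else if (algorithm == "RR") {
        as.numeric(predict(fit, .standardize(X, ctr, scl), type = "response",
                           s = point$lambda))
    } else {
        as.numeric(predict(fit, .standardize(X, ctr, scl)))
    }
}

#' Grid-searched radiomics signature
#'
#' Exhaustive evaluation of the declared grid by internal stratified 5-fold
#' cross-validated AUC on the (balanced) training cohort; ties break to the
#' earliest grid row; the winning point is refit on the full training
#' cohort. Deterministic given the seed.
#'
#' @param algorithm "RF" (random forest), "RR" (ridge logistic regression,
#'   so the score is a probability comparable with the other two) or "ANN"
#'   (single hidden layer, logistic output).
#' @param rset training \linkS4class{RadiomicsSet} (screened, SMOTE-balanced).
#' @param grid data.frame of hyperparameter points; default
#'   [signatureGrid()].
#' @param seed RNG seed for folds, forests and network initialization.
#' @param innerFolds internal CV folds (default 5).
#' @return A \linkS4class{SignatureModel}.
#' @export
gridSearchFit <- function(algorithm = c("RF", "RR", "ANN"), rset, grid = NULL,
                          seed = 1L, innerFolds = 5L) {
    algorithm <- match.arg(algorithm)
    if (is.null(grid)) grid <- signatureGrid(algorithm)
    if (nrow(grid) == 0L) stop("empty hyperparameter grid")
    X <- featureMatrix(rset)
    y <- unname(groupLabels(rset))
    if (min(table(y)) < innerFolds)
        stop("a class is smaller than the number of internal CV folds")
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd); scl[scl == 0] <- 1
    fold <- .stratFolds(y, innerFolds, seed)
    cvAuc <- vapply(seq_len(nrow(grid)), function(gIdx) {
        point <- as.list(grid[gIdx, , drop = FALSE])
        aucs <- vapply(seq_len(innerFolds), function(f) {
            tr <- fold != f
            if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L)
                stop("degenerate labels in an internal CV fold")
            cs <- colMeans(X[tr, , drop = FALSE])
            ss <- apply(X[tr, , drop = FALSE], 2, sd); ss[ss == 0] <- 1
            fit <- .fitPoint(algorithm, X[tr, , drop = FALSE], y[tr], point,
                             cs, ss, seed = seed + 101L * f)
            .aucValue(.scorePoint(algorithm, fit, X[!tr, , drop = FALSE],
                                  point, cs, ss), y[!tr])
        }, numeric(1))
        mean(aucs)
    }, numeric(1))
    best <- which.max(cvAuc)              # first maximum = declared tie-break
    point <- as.list(grid[best, , drop = FALSE])
    fit <- .fitPoint(algorithm, X, y, point, ctr, scl, seed = seed)
    new("SignatureModel", algorithm = algorithm, fit = fit, grid = grid,
        selected = list(point = point, cvAuc = cvAuc[best], allCvAuc = cvAuc),
        featureNames = colnames(X), center = ctr, scale = scl,
        manifest = list(seed = as.integer(seed), n = nrow(X),
                        nFeatures = ncol(X), innerFolds = innerFolds))
}

#' Predict signature scores
#'
#' Columns are matched by feature name (order-free); missing features are an
#' error. RF scores are tree-vote fractions, RR and ANN scores logistic
#' probabilities, all in [0, 1].
#'
#' @param object a \linkS4class{SignatureModel}.
#' @param newdata a \linkS4class{RadiomicsSet} or a subjects-by-features
#'   matrix.
#' @return Named numeric vector of scores in [0, 1].
#' @export
setGeneric("predictScores", function(object, newdata) standardGeneric("predictScores"))

#' @rdname predictScores
#' @export
setMethod("predictScores", "SignatureModel", function(object, newdata) {
    X <- if (is(newdata, "RadiomicsSet")) featureMatrix(newdata) else newdata
    missing <- setdiff(object@featureNames, colnames(X))
    if (length(missing))
        stop("column mismatch: missing features ",
             paste(head(missing, 3), collapse = ", "))
    X <- X[, object@featureNames, drop = FALSE]
    s <- .scorePoint(object@algorithm, object@fit, X, object@selected$point,
                     object@center, object@scale)
    setNames(pmin(pmax(s, 0), 1), rownames(X))
})

#' ROC curve, AUC and DeLong confidence interval
#'
#' The AUC is the tie-aware pairwise concordance (ties count 1/2); the 95
#' percent CI uses the DeLong variance (via pROC), truncated to [0, 1].
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return A \linkS4class{RocResult}.
#' @examples
#' auc(rocAuc(c(.9, .4, .6, .2), c(1, 1, 0, 0)))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L)
        stop("one-class input: ROC needs both classes")
    aucVal <- .aucValue(scores, labels)
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(
        pROC::roc(response = labels, predictor = scores,
                  levels = c(0L, 1L), direction = "<", quiet = TRUE),
        method = "delong")))[c(1L, 3L)]
    ci <- pmin(pmax(ci, 0), 1)
    ci[1] <- min(ci[1], aucVal); ci[2] <- max(ci[2], aucVal)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), numeric(1))
    new("RocResult", auc = aucVal, ci = ci,
        curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr))
}

#' Calibration curve
#'
#' Equal-frequency score groups (tied quantiles merged); per group the mean
#' predicted score is compared with the observed positive fraction.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param nGroups requested number of groups (default 10).
#' @return data.frame(group, n, meanPredicted, observedFraction); the group
#'   sizes sum to the number of subjects.
#' @export
calibrationCurve <- function(scores, labels, nGroups = 10L) {
    if (length(scores) < nGroups)
        stop("too few subjects for ", nGroups, " calibration groups")
    g <- .eqFreqBin(scores, nGroups)
    out <- do.call(rbind, lapply(sort(unique(g)), function(k) {
        data.frame(group = k, n = sum(g == k),
                   meanPredicted = mean(scores[g == k]),
                   observedFraction = mean(labels[g == k] == 1L))
    }))
    stopifnot(sum(out$n) == length(scores))
    out
}
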