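#' Code the fusion design matrix
#'
#' Binary covariates are 0/1-coded (female, left lobe, habit = 1), the
#' continuous ones (age, diameter) standardized; the signature score is kept
#' on its probability scale. Center/scale default to the supplied data
#' (training cohort) and must be reused for held-out subjects.
#'
#' @param clinical data.frame with sex, age, maxDiameter, location, habit
#'   and group.
#' @param score signature scores aligned with \code{clinical} rows (optional).
#' @param center,scale named numeric for age/diameter standardization.
#' @return list(data, center, scale); \code{data} has columns label01,
#'   score (if given), sex, age, diameter, location, habit.
#' @export
prepFusionData <- function(clinical, score = NULL, center = NULL, scale = NULL) {
    if (is.null(center)) center <- c(age = mean(clinical$age),
                                     diameter = mean(clinical$maxDiameter))
    if (is.null(scale)) {
        scale <- c(age = sd(clinical$age), diameter = sd(clinical$maxDiameter))
        scale[scale == 0 | is.na(scale)] <- 1
    }
    df <- data.frame(
        label01 = as.integer(clinical$group == "HEAML"),
        sex = as.integer(clinical$sex == "female"),
        age = (clinical$age - center["age"]) / scale["age"],
        diameter = (clinical$maxDiameter - center["diameter"]) / scale["diameter"],
        location = as.integer(clinical$location == "left"),
        habit = as.integer(clinical$habit == "yes"),
        row.names = rownames(clinical)
    )
    if (!is.null(score)) df$score <- as.numeric(score)
    list(data = df, center = center, scale = scale)
}

# ridge-penalized IRLS logistic fit (no penalty on the intercept);
# fallback for perfect separation
.ridgeLogistic <- function(X, y, lambda = 1e-6, tol = 1e-8, maxit = 200L) {
    beta <- rep(0, ncol(X))
    pen <- rep(lambda, ncol(X)); pen[1] <- 0
    ll <- -Inf
    for (it in seq_len(maxit)) {
        eta <- as.numeric(X %*% beta)
        p <- plogis(eta)
        g <- crossprod(X, y - p) - pen * beta
        W <- pmax(p * (1 - p), 1e-10)
        H <- crossprod(X * W, X) + diag(pen, ncol(X))
        beta <- beta + solve(H, g)
        eta <- as.numeric(X %*% beta)
        # overflow-safe: log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|)
        llNew <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
        if (is.finite(ll) && abs(llNew - ll) < tol) break
        ll <- llNew
    }
    list(beta = as.numeric(beta), logLik = ll)
}

#' Multivariate logistic regression fit
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence |delta logLik| < 1e-8). Perfect separation is detected and
#' the fit ridge-stabilized (penalty 1e-6) and flagged.
#'
#' @param data data.frame from [prepFusionData()] (no missing values).
#' @param covariates covariate column names entering the linear predictor.
#' @param response binary 0/1 response column (default "label01").
#' @return A \linkS4class{FusionModel}.
#' @examples
#' d <- data.frame(label01 = rep(c(0, 1), each = 5), x = rnorm(10))
#' aicValue(fitLogistic(d, character(0)))  # intercept-only: 2 - 2*10*log(0.5)
#' @export
fitLogistic <- function(data, covariates, response = "label01") {
    y <- data[[response]]
    if (length(unique(y)) < 2L)
        stop("degenerate labels: both classes required")
    if (anyNA(data[, c(response, covariates), drop = FALSE]))
        stop("missing values in model data")
    X <- cbind(`(Intercept)` = 1,
               as.matrix(data[, covariates, drop = FALSE]))
    if (qr(X)$rank < ncol(X)) stop("collinear covariates")
    separation <- FALSE
    fml <- if (length(covariates)) y ~ . else y ~ 1
    fit <- withCallingHandlers(
        glm(fml, data = data.frame(y = y, data[, covariates, drop = FALSE]),
            family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100L)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                      conditionMessage(w)))
                separation <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (separation || !fit$converged) {
        rf <- .ridgeLogistic(X, y)
        beta <- setNames(rf$beta, colnames(X))
        ll <- rf$logLik
        separation <- TRUE
    } else {
        beta <- setNames(unname(coef(fit)), colnames(X))
        ll <- as.numeric(logLik(fit))
    }
    rng <- vapply(covariates, function(cv) range(data[[cv]]), numeric(2))
    if (length(covariates) == 0L) rng <- matrix(numeric(0), 2, 0)
    new("FusionModel", covariates = covariates, coefficients = beta,
        logLik = ll, aic = 2 * length(beta) - 2 * ll,
        separation = separation, ranges = rng)
}

#' Predicted HEAML probability of a fusion model
#'
#' @param object a \linkS4class{FusionModel}.
#' @param newdata data.frame containing the model covariates (coded as in
#'   [prepFusionData()]).
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
setMethod("predict", "FusionModel", function(object, newdata, ...) {
    eta <- object@coefficients[1]
    for (cv in object@covariates)
        eta <- eta + object@coefficients[cv] * newdata[[cv]]
    unname(plogis(eta))
})

#' AIC-guided covariate selection for the fusion model
#'
#' Exhaustively refits all 2^5 clinical covariate subsets (the signature
#' score, when present, is forced into every candidate) and returns the
#' lowest-AIC fit. Ties break to fewer covariates, then lexicographically,
#' via the enumeration order.
#'
#' @param data coded data.frame from [prepFusionData()].
#' @param clinical clinical covariate pool.
#' @param scoreCol signature score column forced into every subset; NULL
#'   fits clinical-only models.
#' @param response binary response column.
#' @return The minimal-AIC \linkS4class{FusionModel}.
#' @export
aicSelect <- function(data, clinical = c("sex", "age", "diameter",
                                         "location", "habit"),
                      scoreCol = "score", response = "label01") {
    if (!is.null(scoreCol) && !scoreCol %in% colnames(data))
        stop("signature score column absent: ", scoreCol)
    clinical <- sort(clinical)
    best <- NULL
    for (sz in 0:length(clinical)) {
        subsets <- if (sz == 0L) list(character(0))
                   else combn(clinical, sz, simplify = FALSE)
        for (sub in subsets) {
            m <- fitLogistic(data, c(scoreCol, sub), response = response)
            if (is.null(best) || m@aic < best@aic - 1e-9) best <- m
        }
    }
    best
}

#' Stratified k-fold cross-validation of the fusion pipeline
#'
#' Leakage-free protocol: inside each training fold the feature screening,
#' the nested out-of-fold signature scoring (5 inner folds, fixed random
#' forest configuration) and the AIC covariate selection are all redone from
#' scratch; the held-out fold only ever meets the finished fold model. SMOTE
#' is never applied on this path.
#'
#' @param rset full-cohort \linkS4class{RadiomicsSet} (clinical covariates in
#'   \code{colData}).
#' @param k number of screened features (default 80 CT / 95 MRI, capped at
#'   the panel size).
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed.
#' @param mode "fusion" (signature + AIC-selected clinical), "signature"
#'   (signature score alone) or "clinical" (AIC-selected clinical only).
#' @param rfParams fixed random forest configuration used for the signature
#'   inside the CV.
#' @return list(foldAuc, meanAuc, pooledAuc, predictions) where
#'   \code{meanAuc} is the mean of fold AUCs and \code{pooledAuc} the AUC of
#'   all out-of-fold predictions pooled.
#' @export
crossValidateFusion <- function(rset, k = NULL, folds = 10L, seed = 1L,
                                mode = c("fusion", "signature", "clinical"),
                                rfParams = list(ntree = 300L, nodesize = 1L)) {
    mode <- match.arg(mode)
    y <- unname(groupLabels(rset))
    if (min(table(y)) < folds)
        stop("a class is smaller than the fold count")
    clin <- clinicalData(rset)
    X <- featureMatrix(rset)
    if (is.null(k)) k <- if (identical(modalityTag(rset), "MRI")) 95L else 80L
    k <- min(k, ncol(X))
    fold <- .stratFolds(y, folds, seed)
    predAll <- rep(NA_real_, length(y))
    rfSignature <- function(Xtr, ytr, Xte, s) {
        set.seed(as.integer(s))
        fit <- randomForest::randomForest(
            x = Xtr, y = factor(ytr, levels = c(0L, 1L)),
            ntree = rfParams$ntree, nodesize = rfParams$nodesize)
        unname(predict(fit, Xte, type = "prob")[, "1"])
    }
    foldAuc <- vapply(seq_len(folds), function(f) {
        tr <- which(fold != f); te <- which(fold == f)
        trSet <- rset[, tr]
        kf <- min(k, nrow(rset))
        keep <- mutualInformationRank(trSet)$feature[seq_len(kf)]
        Xtr <- X[tr, keep, drop = FALSE]
        Xte <- X[te, keep, drop = FALSE]
        # nested out-of-fold signature scores on the training part
        oof <- rep(NA_real_, length(tr))
        if (mode != "clinical") {
            inner <- .stratFolds(y[tr], 5L, seed + 13L * f)
            for (g in seq_len(5L)) {
                gi <- inner == g
                oof[gi] <- rfSignature(Xtr[!gi, , drop = FALSE], y[tr][!gi],
                                       Xtr[gi, , drop = FALSE],
                                       seed + 997L * f + g)
            }
        }
        teScore <- if (mode != "clinical")
            rfSignature(Xtr, y[tr], Xte, seed + 31L * f) else NULL
        if (mode == "signature") {
            predAll[te] <<- teScore
            return(.aucValue(teScore, y[te]))
        }
        prepTr <- prepFusionData(clin[tr, , drop = FALSE], score = oof)
        prepTe <- prepFusionData(clin[te, , drop = FALSE], score = teScore,
                                 center = prepTr$center, scale = prepTr$scale)
        model <- if (mode == "fusion")
            aicSelect(prepTr$data, scoreCol = "score")
        else aicSelect(prepTr$data, scoreCol = NULL)
        p <- predict(model, prepTe$data)
        predAll[te] <<- p
        .aucValue(p, y[te])
    }, numeric(1))
    list(foldAuc = foldAuc, meanAuc = mean(foldAuc),
         pooledAuc = .aucValue(predAll, y),
         predictions = setNames(predAll, colnames(rset)))
}

#' Decision curve analysis
#'
#' Net benefit NB(t) = TP/n - FP/n * t/(1-t) with classification score >= t,
#' alongside the treat-all and treat-none (zero) references.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param thresholds threshold probabilities (default 0.01..0.99 by 0.01).
#' @return data.frame(threshold, model, all, none).
#' @export
decisionCurve <- function(scores, labels,
                          thresholds = seq(0.01, 0.99, by = 0.01)) {
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2L) stop("both classes required")
    n <- length(labels)
    prev <- mean(labels)
    nb <- vapply(thresholds, function(t) {
        pos <- scores >= t
        sum(pos & labels == 1L) / n - sum(pos & labels == 0L) / n * t / (1 - t)
    }, numeric(1))
    nbAll <- prev - (1 - prev) * thresholds / (1 - thresholds)
    data.frame(threshold = thresholds, model = nb, all = nbAll, none = 0)
}

#' Build the points-scale nomogram of a fusion model
#'
#' Standard points convention: each covariate's contribution beta * x is
#' mapped affinely onto points with zero at the contribution-minimizing
#' range endpoint; the covariate with the widest contribution range spans
#' 0-100 points; total points map to the predicted probability through the
#' logistic inverse of the reassembled linear predictor.
#'
#' @param model a fitted \linkS4class{FusionModel}.
#' @return A \linkS4class{Nomogram}.
#' @export
buildNomogram <- function(model) {
    stopifnot(is(model, "FusionModel"))
    covs <- model@covariates
    if (length(covs) == 0L) stop("unfitted or intercept-only model")
    beta <- model@coefficients[covs]
    rngs <- model@ranges
    contrib <- abs(beta) * (rngs[2, ] - rngs[1, ])
    maxRange <- max(contrib)
    if (maxRange == 0) maxRange <- 1        # all-null model: 0 points everywhere
    scales <- lapply(covs, function(cv) {
        b <- beta[[cv]]
        ref <- if (b >= 0) rngs[1, cv] else rngs[2, cv]
        list(covariate = cv, beta = unname(b), ref = unname(ref),
             range = unname(rngs[, cv]),
             pointsPerUnit = unname(100 * b / maxRange),
             maxPoints = unname(100 * abs(b) *
                                (rngs[2, cv] - rngs[1, cv]) / maxRange))
    })
    names(scales) <- covs
    offset <- model@coefficients[1] + sum(beta * vapply(scales, `[[`,
                                                        numeric(1), "ref"))
    new("Nomogram", scales = scales, maxRange = maxRange,
        offset = unname(offset))
}

#' Per-covariate nomogram points of subjects
#'
#' @param nomogram a \linkS4class{Nomogram}.
#' @param newdata coded covariate data.frame.
#' @return Matrix of points, one column per covariate plus \code{total}.
#' @export
nomogramPoints <- function(nomogram, newdata) {
    pts <- vapply(nomogram@scales, function(sc) {
        sc$pointsPerUnit * (newdata[[sc$covariate]] - sc$ref)
    }, numeric(nrow(newdata)))
    pts <- matrix(pts, nrow = nrow(newdata),
                  dimnames = list(rownames(newdata), names(nomogram@scales)))
    cbind(pts, total = rowSums(pts))
}

#' Probability from total nomogram points
#'
#' Exact inverse of the points rescaling: equals the fusion model's own
#' predicted probability.
#'
#' @param nomogram a \linkS4class{Nomogram}.
#' @param totalPoints numeric vector of total points.
#' @return HEAML probabilities.
#' @export
nomogramProbability <- function(nomogram, totalPoints) {
    plogis(nomogram@offset + nomogram@maxRange * totalPoints / 100)
}

#' Group comparison of the clinical covariates
#'
#' Continuous covariates (age, maximum diameter) are compared by the
#' two-sided Mann-Whitney U test (normal approximation with tie correction,
#' no continuity correction); categorical covariates (sex, location,
#' alcoholism/smoking) by the two-sided Pearson chi-squared test without
#' continuity correction. p-values are displayed floored at "<0.001".
#'
#' @param records clinical data.frame with \code{group} and the covariates.
#' @return data.frame(variable, heaml, nonHeaml, p, pDisplay).
#' @export
clinicalStats <- function(records) {
    g <- records$group
    if (length(unique(g)) < 2L) stop("empty group: both groups required")
    hi <- g == "HEAML"
    fmtP <- function(p) {
        if (is.na(p)) "-" else if (p < 0.001) "<0.001" else sprintf("%.3f", p)
    }
    rows <- list()
    for (v in c("age", "maxDiameter")) {
        p <- wilcox.test(records[[v]][hi], records[[v]][!hi],
                         exact = FALSE, correct = FALSE)$p.value
        rows[[v]] <- data.frame(
            variable = v,
            heaml = sprintf("%.1f ± %.1f", mean(records[[v]][hi]),
                            sd(records[[v]][hi])),
            nonHeaml = sprintf("%.1f ± %.1f", mean(records[[v]][!hi]),
                               sd(records[[v]][!hi])),
            p = p, pDisplay = fmtP(p), stringsAsFactors = FALSE)
    }
    for (v in c("sex", "location", "habit")) {
        tab <- table(factor(hi, levels = c(TRUE, FALSE)), records[[v]])
        p <- if (ncol(tab) < 2L) NA_real_ else
            suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        lev <- colnames(tab)[1]
        rows[[v]] <- data.frame(
            variable = v,
            heaml = sprintf("%s: %d (%.0f%%)", lev, tab[1, 1],
                            100 * tab[1, 1] / sum(tab[1, ])),
            nonHeaml = sprintf("%s: %d (%.0f%%)", lev, tab[2, 1],
                               100 * tab[2, 1] / sum(tab[2, ])),
            p = p, pDisplay = fmtP(p), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
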