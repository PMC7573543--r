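test_that("stratified split has the 2:1 arithmetic and is deterministic", {
    rset <- syntheticFeatureCohort(nPos = 33L, nNeg = 137L, seed = 2L)
    sp <- stratifiedSplit(rset, seed = 3L)
    grp <- clinicalData(rset)$group
    names(grp) <- colnames(rset)
    expect_equal(sum(grp[testIds(sp)] == "HEAML"), 11L)
    expect_equal(sum(grp[testIds(sp)] == "nonHEAML"), 45L)
    expect_length(intersect(trainIds(sp), testIds(sp)), 0L)
    expect_setequal(c(trainIds(sp), testIds(sp)), colnames(rset))
    expect_identical(stratifiedSplit(rset, seed = 3L), sp)
    expect_false(identical(stratifiedSplit(rset, seed = 4L), sp))

    # degenerate 1:0 ratio keeps everyone in training
    all_train <- stratifiedSplit(rset, ratio = c(1, 0), seed = 1L)
    expect_length(testIds(all_train), 0L)

    tiny <- syntheticFeatureCohort(nPos = 2L, nNeg = 9L, seed = 5L)
    expect_error(stratifiedSplit(tiny, seed = 1L), "too small")
})

test_that("mutual information ranking behaves like the plug-in estimator", {
    # feature = exact copy of a balanced binary label: MI = ln 2
    y <- rep(c(1, 0), each = 50L)
    X <- cbind(copy = y, noise = 0)
    clin <- makeClinical(ifelse(y == 1, "HEAML", "nonHEAML"))
    rset <- radiomicsSet(X, clin)
    rk <- mutualInformationRank(rset)
    expect_equal(rk$mi[rk$feature == "copy"], log(2), tolerance = 1e-12)
    expect_equal(rk$mi[rk$feature == "noise"], 0)     # constant feature
    expect_equal(rk$feature[1], "copy")

    # independent feature at n = 10000: MI < 0.01
    set.seed(8)
    y2 <- rep(c(1, 0), each = 5000L)
    X2 <- cbind(indep = rnorm(10000))
    rset2 <- radiomicsSet(X2, makeClinical(ifelse(y2 == 1, "HEAML",
                                                  "nonHEAML")))
    expect_lt(mutualInformationRank(rset2)$mi[1], 0.01)

    # invariance to strictly monotone transforms (equal-frequency binning)
    rset3 <- syntheticFeatureCohort(nPos = 25L, nNeg = 50L, nFeat = 10L,
                                    seed = 9L)
    rk3 <- mutualInformationRank(rset3)
    Xm <- featureMatrix(rset3)
    Xm[, "f001"] <- exp(3 * Xm[, "f001"])
    Xm[, "f002"] <- Xm[, "f002"]^3
    rk3b <- mutualInformationRank(radiomicsSet(Xm, clinicalData(rset3)))
    expect_equal(rk3b$mi[match(c("f001", "f002"), rk3b$feature)],
                 rk3$mi[match(c("f001", "f002"), rk3$feature)],
                 tolerance = 1e-12)
})

test_that("top-k selection is size-correct and idempotent", {
    rset <- syntheticFeatureCohort(nPos = 20L, nNeg = 40L, nFeat = 30L,
                                   seed = 4L)
    rk <- mutualInformationRank(rset)
    top <- selectTopK(rset, rk, 10L)
    expect_equal(nrow(top), 10L)
    expect_identical(rownames(top), rk$feature[1:10])

    ident <- selectTopK(rset, rk, nrow(rk))
    expect_setequal(rownames(ident), rownames(rset))

    # re-ranking the reduced table reproduces the same top set
    rk2 <- mutualInformationRank(top)
    expect_setequal(mutualInformationRank(selectTopK(top, rk2, 10L))$feature,
                    rk$feature[1:10])

    expect_error(selectTopK(rset, rk, 31L), "out of range")
})

test_that("SMOTE balances by exact convex combinations of minority pairs", {
    # two-point minority: every synthetic sample lies on the segment
    X <- rbind(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
               matrix(rnorm(10, 10), 5, 2))
    colnames(X) <- c("a", "b"); rownames(X) <- sprintf("S%03d", 1:7)
    grp <- c("HEAML", "HEAML", rep("nonHEAML", 5))
    rset <- radiomicsSet(X, makeClinical(grp))
    bal <- smoteBalance(rset, kNeighbors = 1L, seed = 6L)
    syn <- featureMatrix(bal)[clinicalData(bal)$synthetic, , drop = FALSE]
    expect_equal(nrow(syn), 3L)
    expect_equal(syn[, "a"], syn[, "b"], tolerance = 1e-12)  # on {(t,t)}
    expect_true(all(syn[, "a"] >= 0 & syn[, "a"] <= 1))

    # 22 vs 86 -> 86 vs 86, originals preserved, synthetic flagged
    rset2 <- syntheticFeatureCohort(nPos = 22L, nNeg = 86L, nFeat = 8L,
                                    seed = 10L)
    bal2 <- smoteBalance(rset2, seed = 11L)
    expect_equal(as.integer(table(clinicalData(bal2)$group)[c("HEAML", "nonHEAML")]),
                 c(86L, 86L))
    expect_identical(featureMatrix(bal2)[colnames(rset2), ],
                     featureMatrix(rset2))
    expect_equal(sum(clinicalData(bal2)$synthetic), 64L)

    # every synthetic row is an exact convex combination of two minority
    # originals
    Xmin <- featureMatrix(rset2)[clinicalData(rset2)$group == "HEAML", ]
    syn2 <- featureMatrix(bal2)[clinicalData(bal2)$synthetic, ]
    onSegment <- function(srow) {
        for (i in seq_len(nrow(Xmin))) for (j in seq_len(nrow(Xmin))) {
            if (i == j) next
            d <- Xmin[j, ] - Xmin[i, ]
            r <- srow - Xmin[i, ]
            nz <- which(abs(d) > 1e-12)
            if (!length(nz)) next
            u <- r[nz[1]] / d[nz[1]]
            if (u >= -1e-9 && u <= 1 + 1e-9 &&
                max(abs(r - u * d)) < 1e-8) return(TRUE)
        }
        FALSE
    }
    expect_true(all(apply(syn2, 1, onSegment)))

    # determinism and the minority-size precondition
    expect_identical(featureMatrix(smoteBalance(rset2, seed = 11L)),
                     featureMatrix(bal2))
    one <- syntheticFeatureCohort(nPos = 1L, nNeg = 5L, seed = 3L)
    expect_error(smoteBalance(one, seed = 1L), "at least 2")
})

test_that("balancing the training cohort leaves the test cohort untouched", {
    rset <- syntheticFeatureCohort(nPos = 12L, nNeg = 30L, seed = 13L)
    sp <- stratifiedSplit(rset, seed = 13L)
    test <- rset[, testIds(sp)]
    before <- serialize(list(featureMatrix(test), clinicalData(test)), NULL)
    invisible(smoteBalance(rset[, trainIds(sp)], seed = 13L))
    invisible(mutualInformationRank(rset[, trainIds(sp)]))
    after <- serialize(list(featureMatrix(test), clinicalData(test)), NULL)
    expect_identical(before, after)
})
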