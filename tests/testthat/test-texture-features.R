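test_that("first-order features match hand-computed histograms", {
    const <- discretizeRoi(matrix(5, 3, 3), matrix(1L, 3, 3))
    fo <- firstOrderFeatures(const)
    expect_length(fo, 7L)
    expect_equal(unname(fo[c("variance", "entropy", "skewness", "kurtosis")]),
                 c(0, 0, 0, 0))
    expect_equal(fo[["uniformity"]], 1)
    expect_equal(fo[["mean"]], 1)      # constant ROI maps to level 1

    # half level 1, half level 2: entropy 1 bit, uniformity 0.5
    lv <- matrix(rep(c(1L, 2L), each = 8), 4, 4)
    roi <- new("DiscretizedRoi", levels = lv, nBins = 2L, channel = "t")
    fo2 <- firstOrderFeatures(roi)
    expect_equal(fo2[["entropy"]], 1)
    expect_equal(fo2[["uniformity"]], 0.5)
    expect_equal(fo2[["mean"]], 1.5)
    expect_equal(fo2[["variance"]], 0.25)
    expect_equal(fo2[["energy"]], sum(c(rep(1, 8), rep(4, 8))))
})

test_that("GLCM construction and features match exhaustive pair enumeration", {
    # constant 3x3 ROI: single nonzero cell
    const <- discretizeRoi(matrix(1, 3, 3), matrix(1L, 3, 3), nBins = 2)
    m <- computeGlcm(const)
    expect_equal(m[1, 1], 1.0)
    expect_equal(sum(m), 1.0)
    f <- glcmFeatures(m)
    expect_length(f, 9L)
    expect_equal(unname(f[c("contrast", "energy", "entropy", "homogeneity",
                            "correlation")]),
                 c(0, 1, 0, 1, 1))

    # 2x2 [[1,2],[1,2]] against the brute-force oracle
    lv <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
    roi <- new("DiscretizedRoi", levels = lv, nBins = 2L, channel = "t")
    expect_equal(computeGlcm(roi), oracleGlcm(lv, 2L))

    # checkerboard: contrast and sum average against the enumerated matrix
    cb <- matrix(1L + (outer(1:6, 1:6, "+") %% 2L), 6, 6)
    roiCb <- new("DiscretizedRoi", levels = cb, nBins = 2L, channel = "t")
    mo <- oracleGlcm(cb, 2L)
    i <- row(mo); j <- col(mo)
    fCb <- glcmFeatures(computeGlcm(roiCb))
    expect_equal(fCb[["contrast"]], sum((i - j)^2 * mo))
    expect_equal(fCb[["sum_average"]], sum((i + j) * mo))

    # symmetry on random ROIs
    for (s in 1:50) {
        m <- computeGlcm(randomRoi(s))
        expect_identical(m, t(m))
    }
})

test_that("GLRLM runs match manual enumeration", {
    # single row [1,1,1,2], horizontal direction only
    lv <- matrix(c(1L, 1L, 1L, 2L), 1, 4)
    roi <- new("DiscretizedRoi", levels = lv, nBins = 2L, channel = "t")
    horiz <- matrix(c(0L, 1L), 1, 2)
    counts <- computeGlrlm(roi, directions = horiz)
    expect_equal(counts[1, 3], 1)   # one run of level 1, length 3
    expect_equal(counts[2, 1], 1)   # one run of level 2, length 1
    expect_equal(sum(counts), 2)
    f <- glrlmFeatures(counts)
    expect_length(f, 13L)
    expect_equal(f[["rp"]], 2 / 4)

    # constant N-pixel row: single maximal run
    lvc <- matrix(1L, 1, 6)
    roiC <- new("DiscretizedRoi", levels = lvc, nBins = 2L, channel = "t")
    fc <- glrlmFeatures(computeGlrlm(roiC, directions = horiz))
    expect_equal(fc[["sre"]], 1 / 36)
    expect_equal(fc[["lre"]], 36)
})

test_that("GLSZM zones match flood-fill enumeration and conserve mass", {
    # constant ROI of N pixels: one zone, ZP = 1/N
    const <- discretizeRoi(matrix(3, 3, 3), matrix(1L, 3, 3), nBins = 4)
    z <- computeGlszm(const)
    expect_equal(sum(z), 1)
    f <- glszmFeatures(z)
    expect_length(f, 13L)
    expect_equal(f[["zp"]], 1 / 9)

    # two separated single-pixel zones of different levels
    lv <- matrix(0L, 3, 3); lv[1, 1] <- 1L; lv[3, 3] <- 2L
    roi <- new("DiscretizedRoi", levels = lv, nBins = 2L, channel = "t")
    f2 <- glszmFeatures(computeGlszm(roi))
    expect_equal(f2[["zp"]], 1)
    expect_equal(f2[["sze"]], 1)

    # mass conservation on random ROIs
    for (s in 1:50) {
        roi <- randomRoi(s + 500)
        counts <- computeGlszm(roi)
        expect_equal(sum(counts %*% seq_len(ncol(counts))),
                     sum(roiLevels(roi) > 0))
    }
})

test_that("NGTDM matches manual neighbourhood-average computation", {
    const <- discretizeRoi(matrix(2, 3, 3), matrix(1L, 3, 3), nBins = 4)
    f <- ngtdmFeatures(computeNgtdm(const))
    expect_length(f, 5L)
    expect_equal(f[["coarseness"]], 1e6)
    expect_equal(f[["contrast"]], 0)
    expect_equal(f[["busyness"]], 0)

    # 3x3 field of 1s with centre 2: p and s by hand
    lv <- matrix(1L, 3, 3); lv[2, 2] <- 2L
    roi <- new("DiscretizedRoi", levels = lv, nBins = 2L, channel = "t")
    tab <- computeNgtdm(roi)
    # by hand: 8 pixels of level 1 (s contributions vs neighbourhood means)
    # and 1 pixel of level 2 with all-1 neighbourhood -> s_2 = 1
    oracle <- oracleNgtdm(lv, 2L)
    expect_equal(tab$p, oracle$p)
    expect_equal(tab$s, oracle$s, tolerance = 1e-12)
    expect_equal(tab$s[2], 1)
})

test_that("all four texture matrices equal brute force on 100 random ROIs", {
    for (s in 1:100) {
        roi <- randomRoi(s)
        lv <- roiLevels(roi); nb <- nBins(roi)
        expect_equal(computeGlcm(roi), oracleGlcm(lv, nb), tolerance = 1e-12)
        expect_equal(computeGlrlm(roi), oracleGlrlm(lv, nb))
        expect_equal(computeGlszm(roi), oracleGlszm(lv, nb))
        o <- oracleNgtdm(lv, nb); g <- computeNgtdm(roi)
        expect_equal(g$p, o$p, tolerance = 1e-12)
        expect_equal(g$s, o$s, tolerance = 1e-12)
    }
})

test_that("channel panel is stable, rotation-tolerant and mask-localized", {
    roi <- discretizeRoi(matrix(rnorm(144), 12, 12), matrix(1L, 12, 12),
                         nBins = 6, channel = "original")
    v <- channelFeatureSet(roi)
    expect_length(v, 47L)
    expect_identical(v, channelFeatureSet(roi))
    expect_true(all(grepl("^original\\.", names(v))))

    # 90-degree rotation: direction set is rotation-closed
    rot <- new("DiscretizedRoi",
               levels = t(roiLevels(roi))[ncol(roiLevels(roi)):1, ],
               nBins = 6L, channel = "original")
    expect_equal(channelFeatureSet(rot), v, tolerance = 1e-12)

    # out-of-mask values are irrelevant
    img <- matrix(rnorm(100), 10, 10)
    msk <- matrix(0L, 10, 10); msk[3:8, 3:8] <- 1L
    img2 <- img; img2[msk == 0L] <- 999
    expect_identical(
        channelFeatureSet(discretizeRoi(img, msk, nBins = 5)),
        channelFeatureSet(discretizeRoi(img2, msk, nBins = 5)))
})
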