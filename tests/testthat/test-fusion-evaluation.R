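test_that("logistic fit matches closed forms and guards degenerate input", {
    d <- data.frame(label01 = rep(c(1, 0), each = 5))
    m <- fitLogistic(d, character(0))
    expect_equal(m@logLik, 10 * log(0.5), tolerance = 1e-9)
    expect_equal(aicValue(m), 2 - 20 * log(0.5), tolerance = 1e-9)

    expect_error(fitLogistic(data.frame(label01 = rep(0, 8)), character(0)),
                 "degenerate labels")
    dd <- data.frame(label01 = rep(c(1, 0), 5), x = rnorm(10))
    dd$y2 <- 2 * dd$x
    expect_error(fitLogistic(dd, c("x", "y2")), "collinear")

    # perfect separation is flagged and still yields a finite fit
    ds <- data.frame(label01 = rep(c(1, 0), each = 10),
                     x = c(rnorm(10, 5), rnorm(10, -5)))
    ms <- fitLogistic(ds, "x")
    expect_true(ms@separation)
    expect_true(is.finite(aicValue(ms)))

    # agreement with the reference IRLS implementation on a regular fit
    set.seed(40)
    dr <- data.frame(label01 = rbinom(60, 1, 0.5), x = rnorm(60),
                     z = rnorm(60))
    mr <- fitLogistic(dr, c("x", "z"))
    ref <- glm(label01 ~ x + z, dr, family = binomial())
    expect_equal(unname(coef(mr)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(aicValue(mr), AIC(ref), tolerance = 1e-8)
})

test_that("AIC selection equals exhaustive re-enumeration and favours parsimony", {
    set.seed(41)
    n <- 120L
    d <- data.frame(score = runif(n), sex = rbinom(n, 1, 0.5),
                    age = rnorm(n), diameter = rnorm(n),
                    location = rbinom(n, 1, 0.5), habit = rbinom(n, 1, 0.5))
    d$label01 <- rbinom(n, 1, plogis(-1 + 3 * d$score + 1.5 * d$sex))
    sel <- aicSelect(d)
    expect_true("score" %in% fusionCovariates(sel))

    # brute-force oracle over all 32 subsets
    clin <- c("age", "diameter", "habit", "location", "sex")
    allAic <- c()
    for (sz in 0:5) {
        combos <- if (sz == 0) list(character(0)) else
            combn(clin, sz, simplify = FALSE)
        for (sub in combos)
            allAic <- c(allAic, aicValue(fitLogistic(d, c("score", sub))))
    }
    expect_equal(aicValue(sel), min(allAic), tolerance = 1e-9)

    # signal recovery: a strong sex effect is retained in >= 8/10 replicates,
    # pure-noise covariates stay rare
    hits <- 0L; noiseIncl <- 0L
    for (s in 1:10) {
        set.seed(100 + s)
        n2 <- 300L
        d2 <- data.frame(score = runif(n2), sex = rbinom(n2, 1, 0.5),
                         age = rnorm(n2), diameter = rnorm(n2),
                         location = rbinom(n2, 1, 0.5),
                         habit = rbinom(n2, 1, 0.5))
        d2$label01 <- rbinom(n2, 1, plogis(-1 + 2 * d2$score + 2 * d2$sex))
        cv <- fusionCovariates(aicSelect(d2))
        hits <- hits + ("sex" %in% cv)
        noiseIncl <- noiseIncl + length(intersect(cv, c("age", "diameter",
                                                        "location", "habit")))
    }
    expect_gte(hits, 8L)
    expect_lt(noiseIncl / 40, 0.5)   # noise covariates selected well below chance

    # all-noise clinical pool: AIC keeps the selected subsets small
    sizes <- vapply(1:10, function(s) {
        set.seed(200 + s)
        n3 <- 300L
        d3 <- data.frame(score = runif(n3), sex = rbinom(n3, 1, 0.5),
                         age = rnorm(n3), diameter = rnorm(n3),
                         location = rbinom(n3, 1, 0.5),
                         habit = rbinom(n3, 1, 0.5))
        d3$label01 <- rbinom(n3, 1, plogis(-0.5 + 2 * d3$score))
        length(fusionCovariates(aicSelect(d3))) - 1L  # minus forced score
    }, numeric(1))
    expect_lte(mean(sizes), 1.5)
})

test_that("decision curves obey their closed forms and bounds", {
    set.seed(42)
    labels <- rbinom(200, 1, 0.3)
    prev <- mean(labels)
    # treat-all reference
    dca <- decisionCurve(runif(200), labels)
    expect_equal(dca$all, prev - (1 - prev) * dca$threshold /
                            (1 - dca$threshold), tolerance = 1e-12)
    expect_true(all(dca$none == 0))
    # model never beats prevalence
    expect_true(all(dca$model <= prev + 1e-12))
    # perfect scores: NB = prevalence below the score gap
    perfect <- decisionCurve(ifelse(labels == 1, 0.9, 0.1), labels)
    mid <- perfect$threshold > 0.1 & perfect$threshold <= 0.9
    expect_true(all(abs(perfect$model[mid] - prev) < 1e-12))
    # all-positive classification at the smallest threshold -> ~prevalence
    low <- decisionCurve(rep(1, 200), labels, thresholds = 0.01)
    expect_equal(low$model, prev - (1 - prev) * 0.01 / 0.99, tolerance = 1e-12)
    # random instances: NB(perfect) >= NB(model) >= min(NB(all), 0) minus a
    # sampling-noise allowance (the lower bound holds in expectation; at
    # threshold t the NB of a finite sample fluctuates by
    # ~ sqrt(pi(1-pi)/n) * (1 + t/(1-t)))
    for (s in 1:10) {
        set.seed(s)
        lab <- rbinom(80, 1, 0.4); lab[1:2] <- c(0, 1)
        sc <- runif(80)
        d1 <- decisionCurve(sc, lab)
        dPerf <- decisionCurve(ifelse(lab == 1, 1, 0), lab)
        expect_true(all(dPerf$model >= d1$model - 1e-12))
        tol <- 3 * sqrt(0.25 / 80) * (1 + d1$threshold / (1 - d1$threshold))
        expect_true(all(d1$model >= pmin(d1$all, 0) - tol))
    }
})

test_that("nomogram points reassemble the model probability exactly", {
    set.seed(43)
    n <- 150L
    d <- data.frame(score = runif(n), sex = rbinom(n, 1, 0.5),
                    age = rnorm(n), diameter = rnorm(n),
                    location = rbinom(n, 1, 0.5), habit = rbinom(n, 1, 0.5))
    d$label01 <- rbinom(n, 1, plogis(-1 + 2.5 * d$score + d$sex - 0.8 * d$age))
    m <- fitLogistic(d, c("score", "sex", "age", "diameter"))
    nom <- buildNomogram(m)
    pts <- nomogramPoints(nom, d)
    expect_true(all(pts[, colnames(pts) != "total"] >= -1e-9))
    expect_lt(max(abs(nomogramProbability(nom, pts[, "total"]) -
                      predict(m, d))), 1e-9)
    # widest-range covariate spans 0..100
    maxPts <- vapply(nom@scales, `[[`, numeric(1), "maxPoints")
    expect_equal(max(maxPts), 100)

    # single-covariate model: plain logistic curve in disguise
    m1 <- fitLogistic(d, "score")
    n1 <- buildNomogram(m1)
    expect_equal(n1@scales$score$maxPoints, 100)
    p1 <- nomogramPoints(n1, d)
    expect_lt(max(abs(nomogramProbability(n1, p1[, "total"]) -
                      plogis(coef(m1)[1] + coef(m1)["score"] * d$score))),
              1e-9)

    # zero-coefficient covariate earns zero points
    nomZero <- buildNomogram(new("FusionModel", covariates = c("x"),
        coefficients = c(`(Intercept)` = 0.3, x = 0), logLik = -1, aic = 2 * 2 + 2,
        separation = FALSE, ranges = matrix(c(0, 1), 2, 1,
                                            dimnames = list(NULL, "x"))))
    expect_true(all(nomogramPoints(nomZero,
                                   data.frame(x = c(0, 0.5, 1)))[, "x"] == 0))
})

test_that("fusion cross-validation partitions subjects and resists leakage", {
    rset <- syntheticFeatureCohort(nPos = 15L, nNeg = 35L, nFeat = 15L,
                                   delta = 2.5, seed = 50L)
    cv <- crossValidateFusion(rset, k = 10L, folds = 5L, seed = 7L)
    expect_length(cv$foldAuc, 5L)
    expect_true(all(!is.na(cv$predictions)))   # every subject scored once
    expect_equal(cv$meanAuc, mean(cv$foldAuc))
    expect_gt(cv$meanAuc, 0.8)                 # separable features

    expect_error(crossValidateFusion(rset, folds = 16L), "smaller than")

    # canary: deliberately balancing BEFORE the split leaks synthetic
    # near-copies of test rows into training and inflates the test AUC,
    # while the packaged order (balance train only) stays at chance
    leakGap <- vapply(1:3, function(s) {
        null <- syntheticFeatureCohort(nPos = 18L, nNeg = 42L, nFeat = 10L,
                                       nInf = 0L, seed = 60L + s)
        grid <- data.frame(ntree = 100L, nodesize = 1L)
        # packaged order
        sp <- stratifiedSplit(null, seed = s)
        mOk <- gridSearchFit("RF", smoteBalance(null[, trainIds(sp)], seed = s),
                             grid = grid, seed = s)
        aucOk <- auc(rocAuc(predictScores(mOk, null[, testIds(sp)]),
                            groupLabels(null[, testIds(sp)])))
        # contaminated order
        balAll <- smoteBalance(null, seed = s)
        spBad <- stratifiedSplit(balAll, seed = s)
        mBad <- gridSearchFit("RF", balAll[, trainIds(spBad)],
                              grid = grid, seed = s)
        aucBad <- auc(rocAuc(predictScores(mBad, balAll[, testIds(spBad)]),
                             groupLabels(balAll[, testIds(spBad)])))
        aucBad - aucOk
    }, numeric(1))
    expect_gt(mean(leakGap), 0.1)
})

test_that("clinical statistics match the printed-table conventions", {
    # the study's CT sex counts: 6/22 male/female vs 93/35
    rec <- data.frame(
        group = c(rep("HEAML", 28), rep("nonHEAML", 128)),
        sex = c(rep("male", 6), rep("female", 22),
                rep("male", 93), rep("female", 35)),
        age = c(rnorm(28, 47.7, 10.4), rnorm(128, 45.6, 16.3)),
        maxDiameter = c(rnorm(28, 4.4, 1.8), rnorm(128, 5.3, 2.8)),
        location = sample(c("left", "right"), 156, TRUE),
        habit = sample(c("yes", "no"), 156, TRUE))
    st <- clinicalStats(rec)
    expect_lt(st$p[st$variable == "sex"], 0.001)
    expect_equal(st$pDisplay[st$variable == "sex"], "<0.001")

    # identical groups: Mann-Whitney normal approximation gives p = 1
    rec2 <- rec[c(1:20, 1:20), ]
    rec2$group <- rep(c("HEAML", "nonHEAML"), each = 20)
    st2 <- clinicalStats(rec2)
    expect_equal(st2$p[st2$variable == "age"], 1)

    # the reported categorical p equals the closed-form 2x2 chi-squared
    for (s in 1:10) {
        set.seed(s)
        a <- sample(3:30, 4)      # HEAML yes/no, non-HEAML yes/no
        rec3 <- data.frame(
            group = rep(c("HEAML", "nonHEAML"), c(a[1] + a[2], a[3] + a[4])),
            habit = c(rep(c("yes", "no"), c(a[1], a[2])),
                      rep(c("yes", "no"), c(a[3], a[4]))),
            sex = "female", location = "left",
            age = rnorm(sum(a), 50, 5), maxDiameter = rnorm(sum(a), 5, 1))
        hand <- sum(a) * (a[1] * a[4] - a[2] * a[3])^2 /
            ((a[1] + a[2]) * (a[3] + a[4]) * (a[1] + a[3]) * (a[2] + a[4]))
        st3 <- clinicalStats(rec3)
        expect_equal(st3$p[st3$variable == "habit"],
                     pchisq(hand, 1, lower.tail = FALSE), tolerance = 1e-9)
    }

    expect_error(clinicalStats(rec[rec$group == "HEAML", ]), "both groups")
})
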