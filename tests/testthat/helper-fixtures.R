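# In-code fixtures for the model-level tests (no images involved).

makeClinical <- function(groups, seed = 1L) {
    set.seed(seed)
    n <- length(groups)
    data.frame(
        subjectId = sprintf("S%03d", seq_len(n)),
        sex = sample(c("male", "female"), n, TRUE),
        age = runif(n, 30, 70),
        maxDiameter = runif(n, 2, 8),
        location = sample(c("left", "right"), n, TRUE),
        habit = sample(c("yes", "no"), n, TRUE),
        classLabel = ifelse(groups == "HEAML", "HEAML", "HCC"),
        group = groups,
        row.names = sprintf("S%03d", seq_len(n)),
        stringsAsFactors = FALSE
    )
}

# feature cohort with `nInf` informative features shifted by `delta` in the
# HEAML group; remaining features are pure noise
syntheticFeatureCohort <- function(nPos = 30L, nNeg = 60L, nFeat = 20L,
                                   nInf = 5L, delta = 2, seed = 1L,
                                   modality = "CT") {
    set.seed(seed)
    n <- nPos + nNeg
    groups <- c(rep("HEAML", nPos), rep("nonHEAML", nNeg))
    X <- matrix(rnorm(n * nFeat), n, nFeat,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                sprintf("f%03d", seq_len(nFeat))))
    if (nInf > 0)
        X[groups == "HEAML", seq_len(nInf)] <-
            X[groups == "HEAML", seq_len(nInf)] + delta
    radiomicsSet(X, makeClinical(groups, seed = seed + 1L), modality = modality)
}

# quick phantom case for io / feature tests
smallPhantom <- function(seed = 7L, modality = "CT", imageSize = 32L,
                         diameter = 2.2, class = "HEAML") {
    spec <- cohortSpec(modality, imageSize = imageSize, seed = seed)
    generatePhantom(defaultProfiles(modality)[[class]], diameter, spec,
                    subjectSeed = seed)
}
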