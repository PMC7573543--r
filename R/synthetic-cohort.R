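#' Construct a class profile
#'
#' @param classLabel "HEAML", "HCC" or "FNH".
#' @param femaleProb,leftLobeProb,habitProb Bernoulli probabilities of the
#'   binary covariates.
#' @param ageMean,ageSd,diamMean,diamSd Gaussian moments of age (years) and
#'   maximum diameter (cm); draws are truncated at 0 by redrawing.
#' @param texture list(baseIntensity, noiseSd, correlationLength,
#'   heterogeneityAmp) controlling the lesion texture field.
#' @return A validated \linkS4class{ClassProfile}.
#' @examples
#' p <- classProfile("HEAML", 0.79, 47.7, 10.4, 4.4, 1.8, 0.89, 0.11)
#' @export
classProfile <- function(classLabel, femaleProb, ageMean, ageSd, diamMean,
                         diamSd, leftLobeProb, habitProb,
                         texture = list(baseIntensity = 125, noiseSd = 9,
                                        correlationLength = 3,
                                        heterogeneityAmp = 15)) {
    new("ClassProfile", classLabel = classLabel, femaleProb = femaleProb,
        ageMean = ageMean, ageSd = ageSd, diamMean = diamMean,
        diamSd = diamSd, leftLobeProb = leftLobeProb, habitProb = habitProb,
        texture = texture)
}

#' Construct a cohort specification
#'
#' Defaults mirror the modality-specific enrolment of the study population
#' the simulator emulates: 33 HEAML / 78 HCC / 59 FNH for CT and
#' 30 / 77 / 30 for MRI.
#'
#' @param modality "CT" or "MRI".
#' @param nPerClass named vector of subjects per class; default per modality.
#' @param imageSize square image side in pixels.
#' @param pixelSpacing in-plane spacing in mm.
#' @param seed master seed of the cohort.
#' @return A validated \linkS4class{CohortSpec}.
#' @examples
#' cohortSpec("CT", seed = 1)
#' @export
cohortSpec <- function(modality = c("CT", "MRI"), nPerClass = NULL,
                       imageSize = 64L, pixelSpacing = 1.0, seed = 1L) {
    modality <- match.arg(modality)
    if (is.null(nPerClass)) {
        nPerClass <- if (modality == "CT") {
            c(HEAML = 33L, HCC = 78L, FNH = 59L)
        } else {
            c(HEAML = 30L, HCC = 77L, FNH = 30L)
        }
    }
    storage.mode(nPerClass) <- "integer"
    new("CohortSpec", modality = modality, nPerClass = nPerClass,
        imageSize = as.integer(imageSize), pixelSpacing = pixelSpacing,
        seed = as.integer(seed))
}

#' Default class profiles calibrated to the study's clinical table
#'
#' HEAML parameters follow the printed HEAML column of the clinical
#' characteristics table for the chosen modality; the HCC and FNH
#' sub-profiles are package defaults chosen so that their enrolment-weighted
#' mixture reproduces the printed non-HEAML column (HCC male-dominant and
#' older, FNH predominantly female and younger).
#'
#' @param modality "CT" or "MRI".
#' @param texture "separable" gives class-dependent lesion texture (the
#'   documented strong-separation condition); "identical" gives every class
#'   the same texture parameters (the null condition in which image features
#'   carry no class signal).
#' @return Named list of three \linkS4class{ClassProfile} objects.
#' @examples
#' defaultProfiles("CT")
#' @export
defaultProfiles <- function(modality = c("CT", "MRI"),
                            texture = c("separable", "identical")) {
    modality <- match.arg(modality)
    texture <- match.arg(texture)
    tex <- if (texture == "separable") {
        list(
            HEAML = list(baseIntensity = 140, noiseSd = 6,
                         correlationLength = 6, heterogeneityAmp = 25),
            HCC = list(baseIntensity = 118, noiseSd = 10,
                       correlationLength = 2, heterogeneityAmp = 12),
            FNH = list(baseIntensity = 126, noiseSd = 9,
                       correlationLength = 2.5, heterogeneityAmp = 14)
        )
    } else {
        rep(list(list(baseIntensity = 125, noiseSd = 9,
                      correlationLength = 3, heterogeneityAmp = 15)), 3L) |>
            setNames(c("HEAML", "HCC", "FNH"))
    }
    if (modality == "CT") {
        list(
            HEAML = classProfile("HEAML", 0.79, 47.7, 10.4, 4.4, 1.8,
                                 0.89, 0.11, tex$HEAML),
            HCC = classProfile("HCC", 0.10, 52.0, 13.0, 5.8, 2.8,
                               0.40, 0.75, tex$HCC),
            FNH = classProfile("FNH", 0.50, 37.0, 14.0, 4.6, 2.6,
                               0.47, 0.40, tex$FNH)
        )
    } else {
        list(
            HEAML = classProfile("HEAML", 0.73, 49.0, 9.8, 4.3, 2.2,
                                 0.38, 0.19, tex$HEAML),
            HCC = classProfile("HCC", 0.08, 54.0, 11.0, 5.4, 2.8,
                               0.39, 0.55, tex$HCC),
            FNH = classProfile("FNH", 0.51, 41.0, 12.0, 4.3, 2.4,
                               0.39, 0.23, tex$FNH)
        )
    }
}

# positive truncated Gaussian by redraw
.rtruncpos <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    bad <- which(x <= 0)
    while (length(bad)) {
        x[bad] <- rnorm(length(bad), mean, sd)
        bad <- which(x <= 0)
    }
    x
}

#' Draw the clinical covariate table of a phantom cohort
#'
#' Covariates are drawn independently per subject from the class profile:
#' sex, lobe and alcoholism/smoking as Bernoulli, age and maximum diameter
#' as positive-truncated Gaussians. Deterministic given the spec seed.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param profiles named list of \linkS4class{ClassProfile}, one per class
#'   requested in \code{spec}.
#' @return data.frame with one row per subject: subjectId, sex, age,
#'   maxDiameter, location, habit, classLabel, group (HEAML vs nonHEAML).
#' @examples
#' cohort <- generateClinicalCohort(cohortSpec("CT", seed = 7),
#'                                  defaultProfiles("CT"))
#' table(cohort$classLabel)
#' @export
generateClinicalCohort <- function(spec, profiles) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    missing <- setdiff(names(spec@nPerClass), names(profiles))
    if (length(missing))
        stop("configuration error: no profile for class ", paste(missing, collapse = ", "))
    set.seed(spec@seed)
    out <- lapply(names(spec@nPerClass), function(cl) {
        n <- spec@nPerClass[[cl]]
        if (n == 0L) return(NULL)
        p <- profiles[[cl]]
        validObject(p)
        data.frame(
            sex = ifelse(rbinom(n, 1L, p@femaleProb) == 1L, "female", "male"),
            age = .rtruncpos(n, p@ageMean, p@ageSd),
            maxDiameter = .rtruncpos(n, p@diamMean, p@diamSd),
            location = ifelse(rbinom(n, 1L, p@leftLobeProb) == 1L, "left", "right"),
            habit = ifelse(rbinom(n, 1L, p@habitProb) == 1L, "yes", "no"),
            classLabel = cl,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
        return(data.frame(subjectId = character(), sex = character(),
                          age = numeric(), maxDiameter = numeric(),
                          location = character(), habit = character(),
                          classLabel = character(), group = character(),
                          stringsAsFactors = FALSE))
    }
    out$group <- ifelse(out$classLabel == "HEAML", "HEAML", "nonHEAML")
    out <- cbind(subjectId = sprintf("%s_%s_%03d", spec@modality,
                                     out$classLabel, sequence(spec@nPerClass[spec@nPerClass > 0L])),
                 out)
    rownames(out) <- out$subjectId
    out
}

# separable Gaussian smoothing with reflected borders
.gaussSmooth <- function(mat, sigma) {
    k <- max(1L, ceiling(3 * sigma))
    kern <- dnorm(seq(-k, k), sd = sigma)
    kern <- kern / sum(kern)
    n <- nrow(mat)
    idx <- seq_len(n)
    # reflected index table for each shift
    smooth1d <- function(m) {
        acc <- matrix(0, nrow(m), ncol(m))
        for (j in seq_along(kern)) {
            sh <- j - k - 1L
            src <- idx + sh
            src <- ifelse(src < 1L, 2L - src, src)
            src <- ifelse(src > nrow(m), 2L * nrow(m) - src, src)
            acc <- acc + kern[j] * m[src, , drop = FALSE]
        }
        acc
    }
    t(smooth1d(t(smooth1d(mat))))
}

#' Generate one phantom lesion image and its ROI mask
#'
#' The lesion is a filled, axis-aligned ellipse whose major axis (in mm)
#' matches the requested diameter to within one pixel (eccentricity fixed at
#' 0.7). Inside the mask, intensities are base intensity plus a smoothed
#' Gaussian heterogeneity field (kernel SD = correlation length, field
#' standardized then scaled to the heterogeneity amplitude) plus white
#' noise; the background is a distinct constant (55\% of base) plus the same
#' white noise. Gray values are rounded to integers, emulating quantized
#' scanner output.
#'
#' @param profile a \linkS4class{ClassProfile}.
#' @param diameter lesion major axis in cm.
#' @param spec a \linkS4class{CohortSpec} (image size and spacing).
#' @param subjectSeed per-subject seed; output is a pure function of the
#'   arguments.
#' @return A \linkS4class{PhantomCase}.
#' @examples
#' pc <- generatePhantom(defaultProfiles("CT")$HEAML, 4.4,
#'                       cohortSpec("CT"), subjectSeed = 11L)
#' @export
generatePhantom <- function(profile, diameter, spec, subjectSeed) {
    validObject(profile); validObject(spec)
    n <- spec@imageSize
    aPx <- diameter * 10 / spec@pixelSpacing      # major axis in pixels
    if (aPx > n)
        stop("sizing error: lesion (", round(aPx), " px) does not fit image (",
             n, " px)")
    bPx <- 0.7 * aPx
    ctr <- (n + 1) / 2
    cols <- matrix(rep(seq_len(n), each = n), n, n)
    rows <- matrix(rep(seq_len(n), times = n), n, n)
    mask <- ((cols - ctr) / (aPx / 2))^2 + ((rows - ctr) / (bPx / 2))^2 <= 1
    mask <- matrix(as.integer(mask), n, n)
    if (sum(mask) < 9L)
        stop("sizing error: ROI smaller than 9 pixels")
    tx <- profile@texture
    set.seed(as.integer(subjectSeed))
    field <- matrix(0, n, n)
    if (tx$heterogeneityAmp > 0) {
        field <- .gaussSmooth(matrix(rnorm(n * n), n, n), tx$correlationLength)
        rng <- range(field)
        # amplitude = half the peak-to-peak swing of the heterogeneity field
        if (rng[2] > rng[1])
            field <- (2 * (field - rng[1]) / (rng[2] - rng[1]) - 1) *
                tx$heterogeneityAmp
    }
    noise <- if (tx$noiseSd > 0) matrix(rnorm(n * n, sd = tx$noiseSd), n, n)
             else matrix(0, n, n)
    img <- 0.55 * tx$baseIntensity + noise
    inside <- mask == 1L
    img[inside] <- tx$baseIntensity + field[inside] + noise[inside]
    img <- pmin(pmax(round(img), 0), 65535)
    new("PhantomCase", image = img, mask = mask,
        spacing = rep(spec@pixelSpacing, 2L), modality = spec@modality)
}

#' Wrap an image and mask as a PhantomCase
#'
#' @param image numeric matrix of gray values.
#' @param mask binary matrix of the same shape.
#' @param spacing length-2 spacing in mm (a scalar is recycled).
#' @param modality modality tag.
#' @return A validated \linkS4class{PhantomCase}.
#' @export
phantomCase <- function(image, mask, spacing = c(1, 1), modality = "CT") {
    if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
    storage.mode(mask) <- "integer"
    new("PhantomCase", image = image, mask = mask, spacing = as.numeric(spacing),
        modality = modality)
}

#' Embed a 2-D case into a thin 3-D stack
#'
#' Utility for exercising analysis-slice selection: the case's mask is
#' largest on \code{lesionSlice}; neighbouring slices carry shrunken masks.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param nSlices number of slices.
#' @param lesionSlice index of the slice holding the full mask.
#' @return list(volume, maskVolume) of 3-D arrays (row, col, slice).
#' @export
phantomStack <- function(case, nSlices = 3L, lesionSlice = 2L) {
    stopifnot(lesionSlice >= 1L, lesionSlice <= nSlices)
    d <- dim(case@image)
    vol <- array(rep(case@image, nSlices), c(d, nSlices))
    mvol <- array(0L, c(d, nSlices))
    n <- nrow(case@mask)
    ctr <- (n + 1) / 2
    for (s in seq_len(nSlices)) {
        shrink <- 0.5^abs(s - lesionSlice)
        if (shrink == 1) {
            mvol[, , s] <- case@mask
        } else {
            # erode radially by rescaling the mask support toward its centroid
            cols <- matrix(rep(seq_len(n), each = n), n, n)
            rows <- matrix(rep(seq_len(n), times = n), n, n)
            src_r <- pmin(pmax(round(ctr + (rows - ctr) / shrink), 1L), n)
            src_c <- pmin(pmax(round(ctr + (cols - ctr) / shrink), 1L), n)
            mvol[, , s] <- matrix(case@mask[cbind(as.vector(src_r),
                                                  as.vector(src_c))], n, n)
        }
    }
    list(volume = vol, maskVolume = mvol)
}

#' Write a full phantom study to disk
#'
#' Writes one image and one mask per subject (NIfTI by default, 16-bit PNG
#' as a dependency-light dialect), a clinical covariate table keyed by
#' subject id, and a JSON manifest recording the spec, profiles and seed.
#' Re-running with identical arguments reproduces identical files.
#'
#' Lesion masks are drawn at the subject's clinical maximum diameter, capped
#' at 90\% of the field of view so extreme diameter draws still fit the
#' image and floored at 5 pixels so the ROI always supports the texture
#' matrices (>= 9 in-mask pixels); the clinical table keeps the unclipped
#' diameter.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param profiles named profile list as in [generateClinicalCohort()].
#' @param outDir output directory (created if absent).
#' @param format "nifti" (.nii) or "png".
#' @return Invisibly, the manifest list (with element \code{files}).
#' @examples
#' \donttest{
#' d <- generateStudy(cohortSpec("CT", nPerClass = c(HEAML = 2L, HCC = 2L, FNH = 1L)),
#'                    defaultProfiles("CT"), tempfile("study"))
#' }
#' @export
generateStudy <- function(spec, profiles, outDir,
                          format = c("nifti", "png")) {
    format <- match.arg(format)
    validObject(spec)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("output directory not writable: ", outDir)
    cohort <- generateClinicalCohort(spec, profiles)
    files <- data.frame(subjectId = character(), image = character(),
                        mask = character(), stringsAsFactors = FALSE)
    maxDiamCm <- 0.9 * spec@imageSize * spec@pixelSpacing / 10
    minDiamCm <- 5 * spec@pixelSpacing / 10      # keeps the ROI >= 9 pixels
    for (i in seq_len(nrow(cohort))) {
        sid <- cohort$subjectId[i]
        pr <- profiles[[cohort$classLabel[i]]]
        subjectSeed <- (as.numeric(spec@seed) * 10007 + i) %% 2147483647
        case <- generatePhantom(pr,
                                min(max(cohort$maxDiameter[i], minDiamCm),
                                    maxDiamCm),
                                spec, subjectSeed = subjectSeed)
        ext <- if (format == "nifti") ".nii" else ".png"
        imgFile <- file.path(outDir, paste0(sid, "_img", ext))
        mskFile <- file.path(outDir, paste0(sid, "_msk", ext))
        writeCase(case, imgFile, mskFile)
        files <- rbind(files, data.frame(subjectId = sid,
            image = basename(imgFile), mask = basename(mskFile),
            stringsAsFactors = FALSE))
    }
    write.csv(cohort, file.path(outDir, "clinical.csv"), row.names = FALSE)
    manifest <- list(
        seed = spec@seed, modality = spec@modality,
        nPerClass = as.list(spec@nPerClass),
        imageSize = spec@imageSize, pixelSpacing = spec@pixelSpacing,
        format = format,
        profiles = lapply(profiles, function(p) list(
            classLabel = p@classLabel, femaleProb = p@femaleProb,
            ageMean = p@ageMean, ageSd = p@ageSd, diamMean = p@diamMean,
            diamSd = p@diamSd, leftLobeProb = p@leftLobeProb,
            habitProb = p@habitProb, texture = p@texture)),
        files = files
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
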