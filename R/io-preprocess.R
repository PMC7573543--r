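# 16-bit gray values in an 8-bit RGB PNG: R = high byte, G = low byte.
# png::writePNG writes 8 bits per channel only, so a plain gray PNG cannot
# carry quantized scanner-like intensities losslessly.
.writeGrayPng16 <- function(mat, file) {
    v <- pmin(pmax(round(mat), 0), 65535)
    arr <- array(0, c(dim(v), 3L))
    arr[, , 1] <- (v %/% 256) / 255
    arr[, , 2] <- (v %% 256) / 255
    png::writePNG(arr, file)
}

.readGrayPng16 <- function(file) {
    a <- png::readPNG(file)
    if (length(dim(a)) == 2L) return(round(a * 65535))
    round(a[, , 1] * 255) * 256 + round(a[, , 2] * 255)
}

#' Write a case to disk as NIfTI or PNG
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param imageFile,maskFile output paths; extension selects the format
#'   (".nii"/".nii.gz" or ".png").
#' @return Invisibly, \code{c(imageFile, maskFile)}.
#' @seealso [loadCase()]
#' @export
writeCase <- function(case, imageFile, maskFile) {
    validObject(case)
    if (grepl("\\.png$", imageFile)) {
        .writeGrayPng16(case@image, imageFile)
        png::writePNG(case@mask + 0.0, maskFile)
    } else {
        img <- RNifti::asNifti(case@image)
        RNifti::pixdim(img) <- case@spacing
        RNifti::writeNifti(img, imageFile)
        msk <- RNifti::asNifti(case@mask)
        RNifti::pixdim(msk) <- case@spacing
        RNifti::writeNifti(msk, maskFile)
    }
    invisible(c(imageFile, maskFile))
}

#' Load an image/mask pair
#'
#' Reads a NIfTI (.nii/.nii.gz) or PNG pair written by [writeCase()] /
#' [generateStudy()] and returns the aligned case. NIfTI spacing is taken
#' from the header; for PNG it must be supplied.
#'
#' @param imagePath,maskPath file paths.
#' @param spacing spacing in mm for the PNG dialect (ignored for NIfTI).
#' @param modality modality tag to attach.
#' @return A \linkS4class{PhantomCase}.
#' @export
loadCase <- function(imagePath, maskPath, spacing = c(1, 1), modality = "CT") {
    for (f in c(imagePath, maskPath))
        if (!file.exists(f)) stop("unreadable file: ", f)
    if (grepl("\\.png$", imagePath)) {
        img <- .readGrayPng16(imagePath)
        mraw <- png::readPNG(maskPath)
        if (length(dim(mraw)) == 3L) mraw <- mraw[, , 1]
        msk <- matrix(as.integer(mraw > 0.5), nrow(mraw), ncol(mraw))
    } else {
        nimg <- RNifti::readNifti(imagePath)
        nmsk <- RNifti::readNifti(maskPath)
        spacing <- RNifti::pixdim(nimg)[1:2]
        img <- matrix(as.vector(nimg), dim(nimg)[1], dim(nimg)[2])
        msk <- matrix(as.integer(as.vector(nmsk) > 0.5), dim(nmsk)[1], dim(nmsk)[2])
    }
    if (!all(dim(img) == dim(msk))) stop("shape mismatch between image and mask")
    if (sum(msk) == 0L) stop("empty mask: ", maskPath)
    if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
    phantomCase(img, msk, spacing = spacing, modality = modality)
}

#' Load a study directory written by generateStudy
#'
#' @param dir directory containing manifest.json, clinical.csv and the
#'   image/mask files.
#' @return list(cases = named list of \linkS4class{PhantomCase},
#'   clinical = data.frame, manifest = list).
#' @export
loadStudy <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    clinical <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
    rownames(clinical) <- clinical$subjectId
    files <- manifest$files
    cases <- lapply(seq_len(nrow(files)), function(i) {
        loadCase(file.path(dir, files$image[i]), file.path(dir, files$mask[i]),
                 spacing = rep(manifest$pixelSpacing, 2L),
                 modality = manifest$modality)
    })
    names(cases) <- files$subjectId
    list(cases = cases, clinical = clinical, manifest = manifest)
}

#' Select the analysis slice from a thin 3-D stack
#'
#' Returns the slice with the largest in-mask pixel count (the
#' maximum-diameter cross-section protocol); ties break to the lowest slice
#' index. 2-D input passes through unchanged.
#'
#' @param volume 2-D matrix or 3-D array (row, col, slice).
#' @param maskVolume binary mask of the same shape.
#' @return list(image, mask, slice).
#' @export
selectSlice <- function(volume, maskVolume) {
    if (!all(dim(volume) == dim(maskVolume)))
        stop("shape mismatch between volume and mask")
    if (length(dim(volume)) == 2L || is.null(dim(volume))) {
        return(list(image = volume, mask = maskVolume, slice = 1L))
    }
    areas <- apply(maskVolume, 3, sum)
    if (all(areas == 0)) stop("empty mask: no in-mask pixels in any slice")
    k <- which.max(areas)          # which.max takes the first maximum
    list(image = volume[, , k], mask = maskVolume[, , k], slice = as.integer(k))
}

# natural cubic spline along the first dimension onto new coordinates
.splineResample1d <- function(mat, oldCoord, newCoord) {
    apply(mat, 2, function(col) {
        splinefun(oldCoord, col, method = "natural")(newCoord)
    })
}

#' Resample a case onto a target pixel spacing
#'
#' The image is interpolated by separable natural cubic splines onto a grid
#' with the requested spacing (same physical extent); the mask is resampled
#' by nearest neighbour so it stays binary. Exact identity when the spacing
#' already matches to within 1e-9.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param targetSpacing scalar or length-2 target spacing in mm.
#' @return The resampled \linkS4class{PhantomCase}.
#' @export
resampleCase <- function(case, targetSpacing = c(1, 1)) {
    validObject(case)
    if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 2L)
    if (any(targetSpacing <= 0)) stop("targetSpacing must be > 0")
    if (all(abs(case@spacing - targetSpacing) < 1e-9)) return(case)
    d <- dim(case@image)
    newGrid <- function(n, spOld, spNew) {
        extent <- (n - 1) * spOld
        seq(0, extent, by = spNew)
    }
    rOld <- (seq_len(d[1]) - 1) * case@spacing[1]
    cOld <- (seq_len(d[2]) - 1) * case@spacing[2]
    rNew <- newGrid(d[1], case@spacing[1], targetSpacing[1])
    cNew <- newGrid(d[2], case@spacing[2], targetSpacing[2])
    img <- .splineResample1d(case@image, rOld, rNew)
    img <- t(.splineResample1d(t(img), cOld, cNew))
    nnIdx <- function(newCoord, spOld, n) pmin(pmax(round(newCoord / spOld) + 1, 1), n)
    msk <- case@mask[nnIdx(rNew, case@spacing[1], d[1]),
                     nnIdx(cNew, case@spacing[2], d[2]), drop = FALSE]
    if (sum(msk) == 0L) stop("resampled mask is empty")
    phantomCase(img, msk, spacing = targetSpacing, modality = case@modality)
}

#' Discretize in-mask intensities to a fixed number of gray levels
#'
#' Equal-width binning over the in-mask intensity range:
#' bin(x) = floor((x - min) / (max - min) * nBins) + 1, with x = max mapped
#' to nBins and a constant ROI mapped to level 1 everywhere. Out-of-mask
#' pixels are exactly 0.
#'
#' @param image numeric matrix or a \linkS4class{PhantomCase} (then
#'   \code{mask} defaults to its own mask).
#' @param mask binary matrix.
#' @param nBins number of gray levels (>= 2), default 64.
#' @param channel provenance tag stored on the result.
#' @return A \linkS4class{DiscretizedRoi}.
#' @examples
#' img <- matrix(c(10, 20, 30, 40), 2, 2)
#' roiLevels(discretizeRoi(img, matrix(1L, 2, 2), nBins = 4))
#' @export
discretizeRoi <- function(image, mask = NULL, nBins = 64L, channel = "original") {
    if (is(image, "PhantomCase")) {
        if (is.null(mask)) mask <- image@mask
        image <- image@image
    }
    nBins <- as.integer(nBins)
    if (nBins < 2L) stop("nBins must be >= 2")
    inside <- mask == 1L
    if (!any(inside)) stop("empty mask")
    x <- image[inside]
    lv <- matrix(0L, nrow(image), ncol(image))
    rng <- range(x)
    if (rng[1] == rng[2]) {
        lv[inside] <- 1L
    } else {
        b <- floor((x - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L
        b[b > nBins] <- nBins
        lv[inside] <- as.integer(b)
    }
    new("DiscretizedRoi", levels = lv, nBins = nBins, channel = channel)
}
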