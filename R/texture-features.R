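# Distance-1, 4-direction offset set (with symmetrization this covers all 8
# neighbours); closed under 90-degree rotation, so direction-summed matrices
# are invariant to quarter-turns of the ROI.
.defaultOffsets <- function() {
    matrix(c(0L, 1L,
             1L, 0L,
             1L, 1L,
             1L, -1L), ncol = 2L, byrow = TRUE)
}

.checkRoi <- function(roi) {
    stopifnot(is(roi, "DiscretizedRoi"))
    if (!any(roi@levels != 0L)) stop("empty ROI")
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask pixel pairs at the given pixel distance along each
#' direction, symmetrized and summed over directions, normalized to sum 1.
#'
#' @param roi a \linkS4class{DiscretizedRoi}.
#' @param distance pixel distance (default 1).
#' @param directions integer matrix of (row, col) offsets, one per row.
#' @return nBins x nBins normalized symmetric matrix.
#' @seealso [glcmFeatures()]
#' @export
computeGlcm <- function(roi, distance = 1L, directions = .defaultOffsets()) {
    .checkRoi(roi)
    counts <- .cppGlcm(roi@levels, roi@nBins, directions * as.integer(distance))
    tot <- sum(counts)
    if (tot == 0) stop("no valid in-mask pixel pairs for GLCM")
    counts / tot
}

#' The nine co-occurrence features
#'
#' Classical Haralick-style statistics of the normalized symmetric GLCM:
#' contrast, correlation, energy, entropy (log2), homogeneity, variance,
#' sum average, dissimilarity and cluster shade. For a constant ROI (single
#' nonzero cell) the correlation is defined as 1.
#'
#' @param m matrix from [computeGlcm()].
#' @return Named numeric vector of length 9.
#' @export
glcmFeatures <- function(m) {
    n <- nrow(m)
    i <- matrix(rep(seq_len(n), times = n), n, n)
    j <- matrix(rep(seq_len(n), each = n), n, n)
    pi_m <- rowSums(m)                    # symmetric: both margins equal
    mu <- sum(seq_len(n) * pi_m)
    sig2 <- sum((seq_len(n) - mu)^2 * pi_m)
    corr <- if (sig2 <= 0) 1 else sum((i - mu) * (j - mu) * m) / sig2
    pos <- m > 0
    c(contrast = sum((i - j)^2 * m),
      correlation = corr,
      energy = sum(m^2),
      entropy = -sum(m[pos] * log2(m[pos])),
      homogeneity = sum(m / (1 + abs(i - j))),
      variance = sig2,
      sum_average = sum((i + j) * m),
      dissimilarity = sum(abs(i - j) * m),
      cluster_shade = sum((i + j - 2 * mu)^3 * m))
}

#' Gray-level run-length matrix
#'
#' Maximal in-mask same-level runs along each direction, summed over the
#' four distance-1 directions.
#'
#' @inheritParams computeGlcm
#' @return nBins x maxRunLength count matrix.
#' @seealso [glrlmFeatures()]
#' @export
computeGlrlm <- function(roi, directions = .defaultOffsets()) {
    .checkRoi(roi)
    .cppGlrlm(roi@levels, roi@nBins, directions)
}

# shared run/zone statistics: counts matrix indexed level x size
.runZoneFeatures <- function(counts, prefix2) {
    nLev <- nrow(counts); maxSz <- ncol(counts)
    i <- matrix(rep(seq_len(nLev), times = maxSz), nLev, maxSz)
    s <- matrix(rep(seq_len(maxSz), each = nLev), nLev, maxSz)
    N <- sum(counts)
    Np <- sum(counts * s)                 # pixels covered
    p <- counts / N
    muI <- sum(i * p)
    muS <- sum(s * p)
    v <- c(sum(p / s^2),                  # small emphasis
           sum(p * s^2),                  # large emphasis
           sum(rowSums(counts)^2) / N,    # gray-level non-uniformity
           sum(colSums(counts)^2) / N,    # size non-uniformity
           N / Np,                        # percentage
           sum(p / i^2),                  # low gray-level emphasis
           sum(p * i^2),                  # high gray-level emphasis
           sum(p / (i^2 * s^2)),
           sum(p * i^2 / s^2),
           sum(p * s^2 / i^2),
           sum(p * i^2 * s^2),
           sum(p * (i - muI)^2),          # gray-level variance
           sum(p * (s - muS)^2))          # size variance
    names(v) <- prefix2
    v
}

#' The thirteen run-length features
#'
#' SRE, LRE, GLN, RLN, RP, LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE,
#' GLV and RLV by the classical run-length formulas (run counts normalized
#' by the total number of runs; RP = runs / pixels).
#'
#' @param counts matrix from [computeGlrlm()].
#' @return Named numeric vector of length 13.
#' @export
glrlmFeatures <- function(counts) {
    .runZoneFeatures(counts, c("sre", "lre", "gln", "rln", "rp",
                               "lglre", "hglre", "srlgle", "srhgle",
                               "lrlgle", "lrhgle", "glv", "rlv"))
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal gray level inside the mask;
#' cell (i, s) counts zones of level i and size s. Mass conservation holds:
#' sum over cells of size x count equals the in-mask pixel count.
#'
#' @inheritParams computeGlcm
#' @return nBins x maxZoneSize count matrix.
#' @seealso [glszmFeatures()]
#' @export
computeGlszm <- function(roi) {
    .checkRoi(roi)
    zones <- .cppGlszmZones(roi@levels)
    counts <- matrix(0, roi@nBins, max(zones[, 2]))
    for (k in seq_len(nrow(zones)))
        counts[zones[k, 1], zones[k, 2]] <- counts[zones[k, 1], zones[k, 2]] + 1
    counts
}

#' The thirteen size-zone features
#'
#' Size-zone analogues of the run-length set: SZE, LZE, GLN, ZSN, ZP,
#' LGLZE, HGLZE, SZLGLE, SZHGLE, LZLGLE, LZHGLE, GLV and ZSV.
#'
#' @param counts matrix from [computeGlszm()].
#' @return Named numeric vector of length 13.
#' @export
glszmFeatures <- function(counts) {
    .runZoneFeatures(counts, c("sze", "lze", "gln", "zsn", "zp",
                               "lglze", "hglze", "szlgle", "szhgle",
                               "lzlgle", "lzhgle", "glv", "zsv"))
}

#' Neighbourhood gray-tone difference table
#'
#' Amadasun-King table with mask-restricted 3x3 neighbourhoods: for each
#' occurring level i, the occurrence probability p_i (among in-mask pixels
#' with at least one in-mask neighbour) and the summed absolute difference
#' s_i between the level and its neighbourhood mean.
#'
#' @inheritParams computeGlcm
#' @return list(p, s, n) of per-level vectors (length nBins).
#' @seealso [ngtdmFeatures()]
#' @export
computeNgtdm <- function(roi) {
    .checkRoi(roi)
    tab <- .cppNgtdm(roi@levels, roi@nBins)
    N <- sum(tab$n)
    if (N == 0) stop("no in-mask pixel has an in-mask neighbour")
    list(p = tab$n / N, s = tab$s, n = tab$n)
}

#' The five neighbourhood gray-tone difference features
#'
#' Coarseness, contrast, busyness, complexity and strength, with an
#' epsilon = 1e-6 guard on the coarseness, busyness and strength
#' denominators (a constant ROI has all s_i = 0, so coarseness = 1e6 and
#' contrast = busyness = 0).
#'
#' @param tab list from [computeNgtdm()].
#' @return Named numeric vector of length 5.
#' @export
ngtdmFeatures <- function(tab) {
    eps <- 1e-6
    p <- tab$p; s <- tab$s
    N <- sum(tab$n)
    lev <- seq_along(p)
    occ <- which(p > 0)
    ngp <- length(occ)
    pi_ <- p[occ]; si <- s[occ]; li <- lev[occ]
    dIJ <- outer(li, li, "-")
    contrast <- if (ngp > 1) {
        (sum(outer(pi_, pi_) * dIJ^2) / (ngp * (ngp - 1))) * (sum(si) / N)
    } else 0
    busy <- if (ngp > 1) {
        sum(pi_ * si) / (eps + sum(abs(outer(li * pi_, li * pi_, "-"))))
    } else 0
    complexity <- if (ngp > 0) {
        sum(abs(dIJ) * (outer(pi_ * si, pi_ * si, "+")) /
            outer(pi_, pi_, "+")) / N
    } else 0
    strength <- sum(outer(pi_, pi_, "+") * dIJ^2) / (eps + sum(si))
    c(coarseness = 1 / (eps + sum(pi_ * si)),
      contrast = contrast,
      busyness = busy,
      complexity = complexity,
      strength = strength)
}

#' Seven first-order histogram features
#'
#' Computed on the in-mask values of the discretized ROI: mean, population
#' variance, skewness, (non-excess) kurtosis, energy (sum of squared gray
#' levels), entropy (log2) and uniformity. Skewness and kurtosis of a
#' constant ROI are defined as 0.
#'
#' @param roi a \linkS4class{DiscretizedRoi}.
#' @return Named numeric vector of length 7.
#' @export
firstOrderFeatures <- function(roi) {
    .checkRoi(roi)
    x <- as.numeric(roi@levels[roi@levels != 0L])
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
    kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
    p <- tabulate(as.integer(x), roi@nBins) / length(x)
    p <- p[p > 0]
    c(mean = mu,
      variance = m2,
      skewness = skew,
      kurtosis = kurt,
      energy = sum(x^2),
      entropy = -sum(p * log2(p)),
      uniformity = sum(p^2))
}

#' The 47-feature panel of one image channel
#'
#' Concatenates the 7 first-order, 9 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM
#' features of a discretized ROI, namespaced as
#' \code{<channel>.<family>.<feature>}, in a stable order.
#'
#' @param roi a \linkS4class{DiscretizedRoi}.
#' @param channel channel name used in the namespace (defaults to the ROI's
#'   own tag).
#' @return Named numeric vector of length 47.
#' @examples
#' roi <- discretizeRoi(matrix(rnorm(64), 8, 8), matrix(1L, 8, 8), nBins = 4)
#' length(channelFeatureSet(roi))
#' @export
channelFeatureSet <- function(roi, channel = channelName(roi)) {
    fo <- firstOrderFeatures(roi)
    gc <- glcmFeatures(computeGlcm(roi))
    gr <- glrlmFeatures(computeGlrlm(roi))
    gz <- glszmFeatures(computeGlszm(roi))
    ng <- ngtdmFeatures(computeNgtdm(roi))
    v <- c(setNames(fo, paste0(channel, ".firstorder.", names(fo))),
           setNames(gc, paste0(channel, ".glcm.", names(gc))),
           setNames(gr, paste0(channel, ".glrlm.", names(gr))),
           setNames(gz, paste0(channel, ".glszm.", names(gz))),
           setNames(ng, paste0(channel, ".ngtdm.", names(ng))))
    stopifnot(!anyDuplicated(names(v)), all(is.finite(v)))
    v
}
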