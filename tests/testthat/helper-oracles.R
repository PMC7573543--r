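# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops over pixels, runs, zones and pairs.

oracleGlcm <- function(lv, nbins, offsets = rbind(c(0, 1), c(1, 0),
                                                  c(1, 1), c(1, -1))) {
    nr <- nrow(lv); nc <- ncol(lv)
    counts <- matrix(0, nbins, nbins)
    for (k in seq_len(nrow(offsets))) {
        dr <- offsets[k, 1]; dc <- offsets[k, 2]
        for (r in seq_len(nr)) for (c in seq_len(nc)) {
            r2 <- r + dr; c2 <- c + dc
            if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
            a <- lv[r, c]; b <- lv[r2, c2]
            if (a > 0 && b > 0) {
                counts[a, b] <- counts[a, b] + 1
                counts[b, a] <- counts[b, a] + 1
            }
        }
    }
    counts / sum(counts)
}

oracleGlrlm <- function(lv, nbins, offsets = rbind(c(0, 1), c(1, 0),
                                                   c(1, 1), c(1, -1))) {
    nr <- nrow(lv); nc <- ncol(lv)
    counts <- matrix(0, nbins, max(nr, nc))
    inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
    for (k in seq_len(nrow(offsets))) {
        dr <- offsets[k, 1]; dc <- offsets[k, 2]
        for (r in seq_len(nr)) for (c in seq_len(nc)) {
            a <- lv[r, c]
            if (a <= 0) next
            if (inb(r - dr, c - dc) && lv[r - dr, c - dc] == a) next
            len <- 1; r2 <- r + dr; c2 <- c + dc
            while (inb(r2, c2) && lv[r2, c2] == a) {
                len <- len + 1; r2 <- r2 + dr; c2 <- c2 + dc
            }
            counts[a, len] <- counts[a, len] + 1
        }
    }
    counts
}

oracleGlszm <- function(lv, nbins) {
    nr <- nrow(lv); nc <- ncol(lv)
    seen <- matrix(FALSE, nr, nc)
    sizes <- list()
    for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
        a <- lv[r0, c0]
        if (a <= 0 || seen[r0, c0]) next
        queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
        while (length(queue)) {
            p <- queue[[1]]; queue <- queue[-1]
            size <- size + 1
            for (dr in -1:1) for (dc in -1:1) {
                if (dr == 0 && dc == 0) next
                r2 <- p[1] + dr; c2 <- p[2] + dc
                if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
                if (!seen[r2, c2] && lv[r2, c2] == a) {
                    seen[r2, c2] <- TRUE
                    queue <- c(queue, list(c(r2, c2)))
                }
            }
        }
        sizes[[length(sizes) + 1]] <- c(a, size)
    }
    counts <- matrix(0, nbins, max(vapply(sizes, `[`, numeric(1), 2)))
    for (z in sizes) counts[z[1], z[2]] <- counts[z[1], z[2]] + 1
    counts
}

oracleNgtdm <- function(lv, nbins) {
    nr <- nrow(lv); nc <- ncol(lv)
    n <- numeric(nbins); s <- numeric(nbins)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        a <- lv[r, c]
        if (a <= 0) next
        vals <- c()
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            r2 <- r + dr; c2 <- c + dc
            if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
            if (lv[r2, c2] > 0) vals <- c(vals, lv[r2, c2])
        }
        if (length(vals)) {
            n[a] <- n[a] + 1
            s[a] <- s[a] + abs(a - mean(vals))
        }
    }
    list(p = n / sum(n), s = s, n = n)
}

oracleAuc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# random small discretized ROI with an irregular mask
randomRoi <- function(seed, maxSide = 8L, maxLev = 4L) {
    set.seed(seed)
    nr <- sample(3:maxSide, 1); nc <- sample(3:maxSide, 1)
    lv <- matrix(sample(0:maxLev, nr * nc, replace = TRUE,
                        prob = c(0.3, rep(0.7 / maxLev, maxLev))), nr, nc)
    if (sum(lv > 0) < 4) lv[sample(length(lv), 4)] <- sample(maxLev, 4, TRUE)
    # guarantee at least one in-mask neighbour pair (GLCM precondition)
    lv[1, 1] <- max(1L, lv[1, 1]); lv[1, 2] <- max(1L, lv[1, 2])
    new("DiscretizedRoi", levels = lv, nBins = as.integer(maxLev),
        channel = "test")
}
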