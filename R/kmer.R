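# stage 1-2 front end: QC, k-mer spectrum, linked-peak detection,
# bait selection, read extraction

#' Quality-filter read pairs
#'
#' Retains pairs in which both mates have mean Phred quality strictly
#' above `minMeanQ` (the Q-value <= 20 removal rule, interpreted as a
#' mean-Phred threshold per mate).
#'
#' @param reads a [PairedReads] object.
#' @param minMeanQ quality threshold (default 20).
#' @return filtered [PairedReads] with attributes `kept` and `dropped`.
#' @export
qcFilter <- function(reads, minMeanQ = 20) {
    stopifnot(is(reads, "PairedReads"))
    if (length(reads) == 0) {
        attr(reads, "kept") <- 0L
        attr(reads, "dropped") <- 0L
        return(reads)
    }
    m1 <- cpp_mean_qual(reads@qual1)
    m2 <- cpp_mean_qual(reads@qual2)
    keep <- m1 > minMeanQ & m2 > minMeanQ
    out <- reads[which(keep)]
    attr(out, "kept") <- sum(keep)
    attr(out, "dropped") <- sum(!keep)
    out
}

#' Build a canonical k-mer multiplicity spectrum
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement) over all reads; k-mers containing non-ACGT
#' symbols are skipped.
#'
#' @param reads a [PairedReads] object or character vector of sequences.
#' @param k odd word size, at most the read length.
#' @return a [KmerHistogram].
#' @export
buildHistogram <- function(reads, k = 31L) {
    k <- as.integer(k)
    if (k %% 2L == 0L)
        csStop("invalid_parameter", "k must be odd")
    seqs <- readSeqs(reads)
    counts <- cpp_kmer_counts(seqs, k)$count
    tab <- table(counts)
    new("KmerHistogram", k = k, spectrum = data.frame(
        multiplicity = as.integer(names(tab)),
        count = as.integer(tab)))
}

readSeqs <- function(reads) {
    if (is(reads, "PairedReads")) c(reads@seq1, reads@seq2)
    else as.character(reads)
}

# local extrema of a numeric vector with plateau handling. Maxima
# report the plateau midpoint (the peak centre); minima report the
# plateau start — the valley is where the descending signal has died,
# not the middle of a flat desert between peaks.
plateauExtrema <- function(y, maximum = TRUE) {
    r <- rle(y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    v <- r$values
    n <- length(v)
    if (n == 0) return(integer(0))
    left <- c(if (maximum) -Inf else Inf, v[-n])
    right <- c(v[-1], if (maximum) -Inf else Inf)
    hit <- if (maximum) v > left & v > right else v < left & v < right
    if (maximum)
        as.integer(round((starts[hit] + ends[hit]) / 2))
    else
        as.integer(starts[hit])
}

#' Detect the linked single-copy and IR coverage peaks
#'
#' Searches the smoothed k-mer spectrum for the pair of local maxima
#' (N, ~2N) produced by the single-copy and inverted-repeat portions of
#' a plastome at high coverage. Between candidate pairs whose
#' multiplicity ratio lies within `2 +/- ratioTol`, the pair carrying
#' the most k-mer mass wins. The bait band is set to
#' `[max(valley + 1, 0.5 N), 3 N]`.
#'
#' @param hist a [KmerHistogram].
#' @param ratioTol tolerance on the peak ratio around 2.
#' @param minPeakMultiplicity smallest multiplicity considered a peak.
#' @param smoothWidth moving-average window for smoothing.
#' @return a [PeakModel].
#' @export
detectLinkedPeaks <- function(hist, ratioTol = 0.15,
                              minPeakMultiplicity = 5L,
                              smoothWidth = 5L) {
    stopifnot(is(hist, "KmerHistogram"))
    sp <- hist@spectrum
    if (!nrow(sp))
        csStop("no_linked_peaks", "empty spectrum")
    maxMult <- max(sp$multiplicity)
    y <- numeric(maxMult)
    y[sp$multiplicity] <- sp$count
    # centered moving average; edges use the available window
    w <- smoothWidth
    s <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    half <- w %/% 2
    for (i in which(is.na(s))) {
        lo <- max(1L, i - half); hi <- min(maxMult, i + half)
        s[i] <- mean(y[lo:hi])
    }

    maxima <- plateauExtrema(s, maximum = TRUE)
    minima <- plateauExtrema(s, maximum = FALSE)

    # valley: first local minimum after an initial error/nuclear spike
    valley <- 0
    if (length(maxima) && maxima[1] <= minPeakMultiplicity &&
        length(minima)) {
        after <- minima[minima > maxima[1]]
        if (length(after)) valley <- after[1]
    }

    cand <- maxima[maxima > valley & maxima >= minPeakMultiplicity &
                   s[maxima] > 0]
    if (length(cand) < 2)
        csStop("no_linked_peaks", "fewer than two candidate peaks")

    # peak locations are refined to count-weighted centroids before the
    # ratio test: both peaks are broad (fragment sampling overdisperses
    # multiplicities) so a raw local maximum wobbles by several
    # multiplicities. The centroid window recenters on the running
    # estimate until it stabilizes.
    centroid <- function(m) {
        c <- as.numeric(m)
        for (it in 1:5) {
            lo <- max(1L, round(0.8 * c))
            hi <- min(maxMult, round(1.2 * c))
            idx <- seq(lo, hi)
            if (sum(y[idx]) == 0) return(c)
            c2 <- sum(idx * y[idx]) / sum(y[idx])
            if (abs(c2 - c) < 0.1) return(c2)
            c <- c2
        }
        c
    }
    cent <- vapply(cand, centroid, numeric(1))
    mass <- function(m) {
        lo <- max(1L, round(0.8 * m)); hi <- min(maxMult, round(1.2 * m))
        sum(as.numeric(seq(lo, hi)) * y[lo:hi])
    }
    best <- NULL; bestMass <- -Inf
    for (i in seq_along(cand)) for (j in seq_along(cand)) {
        if (j <= i) next
        ratio <- cent[j] / cent[i]
        if (abs(ratio - 2) > ratioTol) next
        mm <- mass(cand[i]) + mass(cand[j])
        if (mm > bestMass) { bestMass <- mm; best <- c(i, j) }
    }
    if (is.null(best))
        csStop("no_linked_peaks",
               "no peak pair with multiplicity ratio near 2")
    nSingle <- cent[best[1]]
    nIr <- cent[best[2]]
    new("PeakModel", nSingle = nSingle, nIr = nIr,
        bandLow = as.integer(max(valley + 1, round(0.5 * nSingle))),
        bandHigh = as.integer(round(3 * nSingle)),
        valley = as.numeric(valley), ratioTol = ratioTol)
}

#' Select bait k-mers from the coverage band
#'
#' Canonical k-mers whose multiplicity lies in the [PeakModel] band
#' `[bandLow, bandHigh]` — the chloroplast single-copy plus IR signal.
#'
#' @param reads a [PairedReads] object or character vector.
#' @param hist the [KmerHistogram] built from `reads` (provides k).
#' @param peaks a [PeakModel].
#' @return a [BaitSet].
#' @export
selectBaitKmers <- function(reads, hist, peaks) {
    stopifnot(is(hist, "KmerHistogram"), is(peaks, "PeakModel"))
    res <- cpp_kmer_counts(readSeqs(reads), hist@k)
    keep <- res$count >= peaks@bandLow & res$count <= peaks@bandHigh
    if (!any(keep))
        csStop("empty_bait_set", "no k-mers in the bait band")
    new("BaitSet", k = hist@k, kmers = res$kmer[keep])
}

#' Extract read pairs matching bait k-mers
#'
#' Keeps a pair when either mate contains at least `minHits` bait
#' k-mers (pair-level baiting preserves insert information for the
#' assembler).
#'
#' @param reads a [PairedReads] object.
#' @param baits a [BaitSet].
#' @param minHits minimum bait k-mer hits in a mate.
#' @return baited [PairedReads].
#' @export
baitReads <- function(reads, baits, minHits = 1L) {
    stopifnot(is(reads, "PairedReads"), is(baits, "BaitSet"))
    if (!length(baits@kmers))
        csStop("empty_bait_set", "bait set is empty")
    h1 <- cpp_bait_hits(reads@seq1, baits@kmers, baits@k)
    h2 <- cpp_bait_hits(reads@seq2, baits@kmers, baits@k)
    reads[which(h1 >= minHits | h2 >= minHits)]
}

#' Write a k-mer spectrum as two-column TSV
#' @param hist a [KmerHistogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHistogram <- function(hist, path) {
    write.table(kmerSpectrum(hist), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Plot a k-mer spectrum with its fitted peaks
#' @param hist a [KmerHistogram].
#' @param peaks optional [PeakModel] to annotate.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotSpectrum <- function(hist, peaks = NULL, ...) {
    sp <- kmerSpectrum(hist)
    graphics::plot(sp$multiplicity, sp$count, type = "h",
                   xlab = "k-mer multiplicity",
                   ylab = "distinct k-mers", ...)
    if (!is.null(peaks)) {
        graphics::abline(v = c(peaks@nSingle, peaks@nIr),
                         col = "red", lty = 2)
        graphics::abline(v = c(peaks@bandLow, peaks@bandHigh),
                         col = "grey50", lty = 3)
    }
    invisible(NULL)
}
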