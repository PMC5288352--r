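# stages 2-5: de Bruijn assembly over a k spread, iterative read
# re-selection, scaffold-end rescue, gap filling

newAssembly <- function(seqs, cov, circular, k, stage) {
    n <- length(seqs)
    new("Assembly", scaffolds = as.character(seqs),
        meta = data.frame(
            id = if (n) paste0("scaffold_", seq_len(n)) else character(0),
            length = nchar(seqs), meanCov = as.numeric(cov),
            circular = as.logical(circular), stringsAsFactors = FALSE),
        k = as.integer(k), stage = stage)
}

#' Assemble reads once at a fixed word size
#'
#' Builds a canonical-k-mer de Bruijn graph, clips low-coverage tips
#' (dead-end unitigs shorter than 2k with coverage below a tenth of the
#' instance-weighted median multiplicity), pops bubbles (parallel paths
#' between the same flanking nodes differing by at most 3 edits; the
#' higher-coverage path is kept) and emits maximal non-branching paths.
#' A single circular non-branching component is emitted once, unrotated.
#'
#' @param reads a [PairedReads] object or character vector of sequences.
#' @param k odd word size, at most the read length.
#' @param tipCovFrac tip coverage threshold as a fraction of the median.
#' @param bubbleDiff maximum edit difference between bubble arms.
#' @return an [Assembly] with stage "initial".
#' @export
assembleOnce <- function(reads, k, tipCovFrac = 0.1, bubbleDiff = 3L) {
    seqs <- readSeqs(reads)
    if (!length(seqs))
        csStop("empty_input", "no reads to assemble")
    k <- as.integer(k)
    if (k %% 2L == 0L)
        csStop("invalid_parameter", "k must be odd")
    if (k > max(nchar(seqs)))
        csStop("invalid_parameter", "k exceeds the read length")
    res <- cpp_assemble(seqs, k, tipCovFrac, bubbleDiff)
    if (!length(res$seq))
        csStop("empty_input", "assembly produced no contigs")
    newAssembly(res$seq, res$cov, res$circular, k, "initial")
}

# ranking used across stages: fewer scaffolds, then total length within
# 0.8-1.2x of the expected size, then larger total, then larger N50
assemblyScoreKey <- function(a, expectedSize = NULL) {
    tot <- sum(nchar(gsub("N", "", a@scaffolds)))
    inBand <- if (is.null(expectedSize)) 0 else
        as.integer(tot >= 0.8 * expectedSize & tot <= 1.2 * expectedSize)
    c(-length(a@scaffolds), inBand, tot, assemblyN50(a))
}

scoreBetter <- function(a, b, expectedSize = NULL) {
    ka <- assemblyScoreKey(a, expectedSize)
    kb <- assemblyScoreKey(b, expectedSize)
    for (i in seq_along(ka)) {
        if (ka[i] > kb[i]) return(TRUE)
        if (ka[i] < kb[i]) return(FALSE)
    }
    FALSE
}

#' Assemble over a word-size spread and keep the best candidate
#'
#' Runs [assembleOnce()] for each k and scores the candidates: fewest
#' scaffolds first, then total length within 0.8-1.2x of
#' `expectedSize` (when provided), then N50.
#'
#' @param reads a [PairedReads] object or character vector.
#' @param kValues odd word sizes to try; values exceeding the read
#'   length are skipped.
#' @param expectedSize expected genome size in bp (optional).
#' @param ... passed to [assembleOnce()].
#' @return the best-scoring [Assembly]; its `k` records the winner.
#' @export
assembleSpread <- function(reads, kValues = c(31L, 41L, 51L, 63L),
                           expectedSize = NULL, ...) {
    seqs <- readSeqs(reads)
    if (!length(seqs))
        csStop("empty_input", "no reads to assemble")
    kValues <- kValues[kValues <= max(nchar(seqs))]
    if (!length(kValues))
        csStop("invalid_parameter",
               "all k values exceed the read length")
    best <- NULL
    for (k in kValues) {
        cand <- assembleOnce(reads, k, ...)
        if (is.null(best) || scoreBetter(cand, best, expectedSize))
            best <- cand
    }
    best
}

# pairs with >= minHits exact shared k-mers (either mate) with the given
# sequences, at word size k
selectReadsBySequence <- function(reads, seqs, k, minHits = 1L) {
    kmers <- cpp_kmer_counts(seqs, k)$kmer
    h1 <- cpp_bait_hits(reads@seq1, kmers, k)
    h2 <- cpp_bait_hits(reads@seq2, kmers, k)
    reads[which(h1 >= minHits | h2 >= minHits)]
}

#' Iteratively re-select reads and reassemble
#'
#' Each iteration selects from the full QC-passed read set the pairs
#' sharing at least one exact k-mer with the current assembly,
#' reassembles at the recorded k, and stops when the total assembled
#' length changes by less than `tol` (0.1%) or after `maxIter`
#' iterations. Never returns an assembly scoring worse than its input.
#'
#' @param assembly the current [Assembly].
#' @param allReads all QC-passed reads (a [PairedReads]), not only the
#'   baited subset.
#' @param maxIter maximum number of refinement iterations.
#' @param tol relative length-change convergence threshold.
#' @param expectedSize optional expected genome size for scoring.
#' @return refined [Assembly] (stage "refined") with attribute
#'   `converged`.
#' @export
refineIteratively <- function(assembly, allReads, maxIter = 5L,
                              tol = 0.001, expectedSize = NULL) {
    stopifnot(is(assembly, "Assembly"), is(allReads, "PairedReads"))
    if (maxIter <= 0L) return(assembly)
    best <- assembly
    cur <- assembly
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        sel <- selectReadsBySequence(allReads, cur@scaffolds, cur@k)
        if (length(sel) == 0) break
        cand <- assembleOnce(sel, cur@k)
        cand@stage <- "refined"
        change <- abs(sum(nchar(cand@scaffolds)) -
                      sum(nchar(cur@scaffolds))) /
            max(1, sum(nchar(cur@scaffolds)))
        if (scoreBetter(cand, best, expectedSize)) best <- cand
        cur <- cand
        if (change < tol) { converged <- TRUE; break }
    }
    out <- if (scoreBetter(best, assembly, expectedSize)) best else {
        cur2 <- assembly
        cur2
    }
    if (out@stage == "initial" && !identical(out, assembly))
        out@stage <- "refined"
    if (!converged)
        attr(out, "warningFlag") <- "refinement did not converge"
    attr(out, "converged") <- converged
    out
}

# mismatches allowed in an overlap of ov bases: 1 per 100 bp
allowedMismatches <- function(ov) floor(ov / 100)

# try to extend the right end of `scaf` with a local contig that
# overlaps it by >= k bases (exact k-seed, <= 1 mismatch / 100 bp over
# the full overlap); returns the extended scaffold
extendRight <- function(scaf, contigs, k) {
    L <- nchar(scaf)
    if (L < k) return(scaf)
    term <- substr(scaf, L - k + 1L, L)
    bestExt <- ""
    for (ct in unique(c(contigs, revComp(contigs)))) {
        hits <- gregexpr(term, ct, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (p in hits) {
            ov <- min(L, p + k - 1L)
            scafPart <- substr(scaf, L - ov + 1L, L)
            contPart <- substr(ct, p + k - ov, p + k - 1L)
            if (hammingDist(scafPart, contPart) > allowedMismatches(ov))
                next
            ext <- substr(ct, p + k, nchar(ct))
            if (nchar(ext) > nchar(bestExt) ||
                (nchar(ext) == nchar(bestExt) && ext < bestExt))
                bestExt <- ext
        }
    }
    paste0(scaf, bestExt)
}

#' Rescue scaffold ends with locally re-selected reads
#'
#' For each scaffold end, collects pairs in which a mate shares a
#' k-mer with the terminal `endWindow` bases, locally assembles them,
#' and extends the scaffold when a local contig overlaps the end by at
#' least k bases with at most 1 mismatch per 100 bp. Scaffolds whose
#' extended ends then overlap each other are merged. This counteracts
#' locally thin representation of the plastome in the library.
#'
#' @param assembly an [Assembly].
#' @param allReads all QC-passed reads.
#' @param endWindow window at each scaffold end used to recruit pairs.
#' @return an [Assembly] with stage "rescued".
#' @export
rescueScaffoldEnds <- function(assembly, allReads, endWindow = 500L) {
    stopifnot(is(assembly, "Assembly"), is(allReads, "PairedReads"))
    k <- assembly@k
    scafs <- assembly@scaffolds
    covs <- assembly@meta$meanCov
    circ <- assembly@meta$circular
    for (i in seq_along(scafs)) {
        if (circ[i]) next
        for (side in c("right", "left")) {
            s <- if (side == "right") scafs[i] else revComp(scafs[i])
            L <- nchar(s)
            win <- substr(s, max(1L, L - endWindow + 1L), L)
            sel <- selectReadsBySequence(allReads, win, k)
            if (length(sel) == 0) next
            loc <- tryCatch(cpp_assemble(readSeqs(sel), k, 0.1, 3L),
                            error = function(e) NULL)
            if (is.null(loc) || !length(loc$seq)) next
            s2 <- extendRight(s, loc$seq, k)
            # only accept extensions that add sequence absent from the
            # rest of the assembly: an "extension" whose k-mers already
            # live in another scaffold is a repeat boundary (e.g. the
            # collapsed IR), not missing sequence
            if (nchar(s2) > L && length(scafs) > 1L) {
                ext <- substr(s2, L + 1L, nchar(s2))
                if (nchar(ext) >= k) {
                    others <- cpp_kmer_counts(scafs[-i], k)$kmer
                    if (cpp_bait_hits(ext, others, k)[1] > 0)
                        s2 <- s
                } else s2 <- s
            }
            scafs[i] <- if (side == "right") s2 else revComp(s2)
        }
    }
    # merge scaffolds whose ends now overlap by >= k bases
    repeat {
        merged <- FALSE
        n <- length(scafs)
        if (n < 2) break
        for (i in seq_len(n)) {
            for (j in seq_len(n)) {
                if (i == j) next
                # a collapsed repeat (about twice single-copy coverage)
                # must not be consumed by an end merge; resolving it is
                # the quadripartite module's job
                covRatio <- max(covs[i], covs[j]) /
                    max(1e-9, min(covs[i], covs[j]))
                if (covRatio > 1.5) next
                a <- scafs[i]
                La <- nchar(a)
                if (La < k) next
                term <- substr(a, La - k + 1L, La)
                for (bs in c(scafs[j], revComp(scafs[j]))) {
                    p <- regexpr(term, bs, fixed = TRUE)[1]
                    if (p == -1L) next
                    ov <- p + k - 1L
                    if (ov > La) next
                    aPart <- substr(a, La - ov + 1L, La)
                    bPart <- substr(bs, 1L, ov)
                    if (hammingDist(aPart, bPart) >
                        allowedMismatches(ov)) next
                    scafs[i] <- paste0(a, substr(bs, ov + 1L, nchar(bs)))
                    covs[i] <- (covs[i] * La + covs[j] *
                                nchar(scafs[j])) /
                        (La + nchar(scafs[j]))
                    scafs <- scafs[-j]
                    covs <- covs[-j]
                    circ <- circ[-j]
                    merged <- TRUE
                    break
                }
                if (merged) break
            }
            if (merged) break
        }
        if (!merged) break
    }
    out <- newAssembly(scafs, covs, circ, k, "rescued")
    out
}

#' Fill scaffold gaps by local assembly
#'
#' For each N-run gap, selects pairs whose mates share k-mers with the
#' gap flanks (up to `2 * insertMean` bp each side), locally assembles
#' them, and splices in a contig that bridges both flanks with exact
#' k-base anchors. Gaps without a bridging contig keep their N-run.
#'
#' @param assembly an [Assembly] whose scaffolds may contain N runs.
#' @param allReads all QC-passed reads.
#' @param insertMean library insert size (defines the flank width).
#' @return an [Assembly] with stage "gapfilled" and attribute
#'   `gapsRemaining`.
#' @export
fillGaps <- function(assembly, allReads, insertMean = 400) {
    stopifnot(is(assembly, "Assembly"), is(allReads, "PairedReads"))
    k <- assembly@k
    flankW <- as.integer(2 * insertMean)
    scafs <- assembly@scaffolds
    remaining <- 0L
    for (i in seq_along(scafs)) {
        repeat {
            s <- scafs[i]
            m <- regexpr("N+", s)
            if (m[1] == -1L) break
            gs <- m[1]
            ge <- gs + attr(m, "match.length") - 1L
            left <- substr(s, max(1L, gs - flankW), gs - 1L)
            right <- substr(s, ge + 1L, min(nchar(s), ge + flankW))
            fill <- NULL
            if (nchar(left) >= k && nchar(right) >= k) {
                sel <- selectReadsBySequence(allReads, c(left, right), k)
                if (length(sel)) {
                    loc <- tryCatch(
                        cpp_assemble(readSeqs(sel), k, 0.1, 3L),
                        error = function(e) NULL)
                    if (!is.null(loc) && length(loc$seq)) {
                        lAnch <- substr(left, nchar(left) - k + 1L,
                                        nchar(left))
                        rAnch <- substr(right, 1L, k)
                        for (ct in c(loc$seq, revComp(loc$seq))) {
                            p1 <- regexpr(lAnch, ct, fixed = TRUE)[1]
                            p2 <- regexpr(rAnch, ct, fixed = TRUE)[1]
                            if (p1 == -1L || p2 == -1L || p2 <= p1) next
                            fill <- substr(ct, p1 + k, p2 - 1L)
                            break
                        }
                    }
                }
            }
            if (is.null(fill)) {
                remaining <- remaining + 1L
                # mask this gap so the loop advances, restore after
                substr(s, gs, ge) <- paste(rep("n", ge - gs + 1L),
                                           collapse = "")
                scafs[i] <- s
                next
            }
            scafs[i] <- paste0(substr(s, 1L, gs - 1L), fill,
                               substr(s, ge + 1L, nchar(s)))
        }
        scafs[i] <- gsub("n", "N", scafs[i])
    }
    out <- newAssembly(scafs, assembly@meta$meanCov,
                       assembly@meta$circular, k, "gapfilled")
    attr(out, "gapsRemaining") <- remaining
    out
}

#' Write an assembly report as TSV
#' @param assemblies list of [Assembly] objects (named by stage or
#'   arbitrary labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssemblyReport <- function(assemblies, path) {
    if (is(assemblies, "Assembly")) assemblies <- list(assemblies)
    rows <- lapply(assemblies, function(a) data.frame(
        stage = a@stage, scaffolds = length(a@scaffolds),
        totalLength = sum(nchar(a@scaffolds)),
        n50 = assemblyN50(a), k = a@k, stringsAsFactors = FALSE))
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write assembly scaffolds as FASTA
#' @param assembly an [Assembly].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAssemblyFasta <- function(assembly, path) {
    writeFasta(scaffolds(assembly), path)
}
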