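# synthetic quadripartite genomes, mutated accessions and paired-end reads

# consecutive LSC, IRa, SSC, IRb spans starting at position 1
regionMapFromLengths <- function(lscLen, irLen, sscLen) {
    starts <- cumsum(c(1L, lscLen, irLen, sscLen))
    new("RegionMap",
        spans = data.frame(
            region = c("LSC", "IRa", "SSC", "IRb"),
            start = as.integer(starts),
            end = as.integer(starts + c(lscLen, irLen, sscLen, irLen) - 1L),
            length = as.integer(c(lscLen, irLen, sscLen, irLen)),
            stringsAsFactors = FALSE),
        totalLength = as.integer(lscLen + sscLen + 2L * irLen))
}

#' Simulate a circular quadripartite plastome
#'
#' Generates a random circular genome with the canonical four-part
#' architecture LSC, IRa, SSC, IRb in which IRa is the exact reverse
#' complement of IRb. Defaults reproduce the reference plastome
#' dimensions of *Brassica rapa* (LSC 83,282 bp, SSC 17,776 bp, IRs of
#' 26,212 bp each; 153,482 bp in total).
#'
#' @param lscLen,sscLen,irLen region lengths in bp (`irLen` per IR copy).
#' @param gcFraction GC content of the random sequence, in (0, 1).
#' @param seed integer seed; identical seeds give identical genomes.
#' @return a [SimulatedGenome].
#' @examples
#' g <- simulateGenome(8000, 2000, 3000, 0.36, seed = 7)
#' regionSpans(g)
#' @export
simulateGenome <- function(lscLen = 83282L, sscLen = 17776L,
                           irLen = 26212L, gcFraction = 0.36,
                           seed = 1L) {
    if (any(c(lscLen, sscLen, irLen) <= 0))
        csStop("invalid_parameter", "region lengths must be positive")
    if (lscLen <= sscLen)
        csStop("invalid_parameter", "LSC must be longer than SSC")
    if (gcFraction <= 0 || gcFraction >= 1)
        csStop("invalid_parameter", "gcFraction must be in (0, 1)")
    set.seed(seed)
    lsc <- randomDNA(lscLen, gcFraction)
    ira <- randomDNA(irLen, gcFraction)
    ssc <- randomDNA(sscLen, gcFraction)
    # make the planted IR maximal: the bases flanking the IR copies must
    # not extend the exact inverted match (outward across the origin,
    # inward across the SSC), otherwise repeat detection would recover
    # slightly larger spans than planted
    comp1 <- function(b) chartr("ACGT", "TGCA", b)
    if (substr(lsc, lscLen, lscLen) == comp1(substr(lsc, 1L, 1L)))
        substr(lsc, lscLen, lscLen) <-
            setdiff(c("A", "C", "G", "T"),
                    comp1(substr(lsc, 1L, 1L)))[1]
    if (substr(ssc, 1L, 1L) == comp1(substr(ssc, sscLen, sscLen)))
        substr(ssc, sscLen, sscLen) <-
            setdiff(c("A", "C", "G", "T"),
                    comp1(substr(ssc, 1L, 1L)))[1]
    new("SimulatedGenome",
        sequence = paste0(lsc, ira, ssc, revComp(ira)),
        regionMap = regionMapFromLengths(lscLen, irLen, sscLen),
        provenance = "simulated", seed = as.integer(seed))
}

# truncated geometric indel lengths: single-base events dominate,
# sizes capped at maxLen (observed plastome InDels run 1-38 bp)
sampleIndelLengths <- function(n, maxLen, p = 0.5) {
    if (n == 0L) return(integer(0))
    probs <- stats::dgeom(seq_len(maxLen) - 1L, p)
    sample.int(maxLen, n, replace = TRUE, prob = probs)
}

#' Mutate a quadripartite genome into an accession
#'
#' Applies region-specific SNV and InDel mutations to a parent genome.
#' Mutations sampled in the IR are placed on IRa and mirrored into IRb
#' (reverse-complemented, coordinates reflected) so the IR identity is
#' preserved; both copies are logged. Candidate mutations closer than
#' `minSpacing` bp to an already accepted one are rejected (and counted)
#' to keep truth/call matching unambiguous.
#'
#' @param genome a [QuadripartiteGenome] (e.g. from [simulateGenome()]).
#' @param snvRate,indelRate named per-bp rates for regions `LSC`, `SSC`,
#'   `IR`. The IR rate applies per copy; the mirror doubles the count.
#' @param maxIndelLen maximum InDel length (default 38 bp).
#' @param minSpacing minimum distance in bp between mutations.
#' @param seed integer seed.
#' @param accession accession identifier recorded in the log.
#' @return list with `sequence` (mutated accession), `log` (data.frame
#'   `accession`, `pos`, `ref`, `alt`, `class`, `mirrored`; positions are
#'   1-based on the parent, InDels anchor-base left-aligned by
#'   construction position), and `rejected` (count of spacing
#'   rejections).
#' @seealso [applyMutationLog()]
#' @export
mutateGenome <- function(genome,
                         snvRate = c(LSC = 0.003, SSC = 0.004,
                                     IR = 5e-04),
                         indelRate = c(LSC = 8e-04, SSC = 8e-04,
                                       IR = 1e-04),
                         maxIndelLen = 38L, minSpacing = 31L,
                         seed = 1L, accession = "acc1") {
    stopifnot(is(genome, "QuadripartiteGenome"))
    rates <- c(snvRate, indelRate)
    if (any(rates < 0))
        csStop("invalid_parameter", "rates must be >= 0")
    if (any(rates > 0.5))
        csStop("invalid_parameter",
               "rates > 0.5 would give unalignable output")
    parent <- genome@sequence
    L <- nchar(parent)
    sp <- genome@regionMap@spans
    span <- function(r) unlist(sp[sp$region == r, c("start", "end")])
    ira <- span("IRa"); irb <- span("IRb")
    baseAt <- function(p) substr(parent, p, p)
    refAt <- function(p, len) substr(parent, p, p + len - 1L)
    mirrorPos <- function(q) irb[["end"]] - (q - ira[["start"]])

    set.seed(seed)
    events <- list()
    blocked <- logical(L)
    rejected <- 0L
    bases <- c("A", "C", "G", "T")

    # an event and its IR mirror are accepted or rejected together so
    # the IR identity is never broken by a one-sided rejection
    addEvents <- function(evs) {
        for (e in evs) {
            a <- e$pos; b <- e$pos + nchar(e$ref) - 1L
            if (any(blocked[a:b])) {
                rejected <<- rejected + 1L
                return(invisible(FALSE))
            }
        }
        for (e in evs) {
            a <- e$pos; b <- e$pos + nchar(e$ref) - 1L
            lo <- max(1L, a - minSpacing); hi <- min(L, b + minSpacing)
            blocked[lo:hi] <<- TRUE
            events[[length(events) + 1L]] <<- data.frame(
                pos = e$pos, ref = e$ref, alt = e$alt, class = e$class,
                mirrored = e$mirrored, stringsAsFactors = FALSE)
        }
        invisible(TRUE)
    }
    ev <- function(pos, ref, alt, class, mirrored)
        list(pos = pos, ref = ref, alt = alt, class = class,
             mirrored = mirrored)

    for (region in c("LSC", "SSC", "IRa")) {
        rateKey <- if (region == "IRa") "IR" else region
        rs <- span(region)
        # keep events (and anchors) strictly inside the region so a
        # variant's position assigns unambiguously and IR mirrors stay
        # inside IRb
        lo <- rs[["start"]] + 1L
        hi <- rs[["end"]] - 1L
        nPos <- hi - lo + 1L
        if (nPos <= 0) next

        nSnv <- rbinom(1L, nPos, snvRate[[rateKey]])
        posS <- sort(sample.int(nPos, min(nSnv, nPos))) + lo - 1L
        for (p in posS) {
            ref <- baseAt(p)
            if (!ref %in% bases) next
            alt <- sample(setdiff(bases, ref), 1L)
            evs <- list(ev(p, ref, alt, "SNV", FALSE))
            if (region == "IRa")
                evs <- c(evs, list(ev(mirrorPos(p), revComp(ref),
                                      revComp(alt), "SNV", TRUE)))
            addEvents(evs)
        }

        nInd <- rbinom(1L, nPos, indelRate[[rateKey]])
        posI <- sort(sample.int(nPos, min(nInd, nPos))) + lo - 1L
        lens <- sampleIndelLengths(length(posI), maxIndelLen)
        isIns <- runif(length(posI)) < 0.5
        for (j in seq_along(posI)) {
            p <- posI[j]; d <- lens[j]
            if (isIns[j]) {
                if (p >= hi) next
                ins <- randomDNA(d, 0.5)
                ref <- baseAt(p)
                evs <- list(ev(p, ref, paste0(ref, ins), "INS", FALSE))
                if (region == "IRa") {
                    # insertion after p maps to insertion after
                    # mirrorPos(p) - 1 with the insert reverse-complemented
                    mp <- mirrorPos(p) - 1L
                    evs <- c(evs, list(ev(mp, baseAt(mp),
                                          paste0(baseAt(mp), revComp(ins)),
                                          "INS", TRUE)))
                }
                addEvents(evs)
            } else {
                # delete bases p+1 .. p+d, anchored at p
                if (p + d > hi) next
                ref <- refAt(p, d + 1L)
                evs <- list(ev(p, ref, baseAt(p), "DEL", FALSE))
                if (region == "IRa") {
                    mp <- mirrorPos(p + d) - 1L
                    evs <- c(evs, list(ev(mp, refAt(mp, d + 1L),
                                          baseAt(mp), "DEL", TRUE)))
                }
                addEvents(evs)
            }
        }
    }

    log <- if (length(events)) do.call(rbind, events) else
        data.frame(pos = integer(0), ref = character(0),
                   alt = character(0), class = character(0),
                   mirrored = logical(0), stringsAsFactors = FALSE)
    log <- log[order(log$pos), , drop = FALSE]
    rownames(log) <- NULL
    log <- cbind(accession = rep(accession, nrow(log)), log,
                 stringsAsFactors = FALSE)
    list(sequence = applyMutationLog(parent, log), log = log,
         rejected = rejected)
}

#' Apply a mutation log to a parent genome
#'
#' Replays the events of a [mutateGenome()] log (or any data.frame with
#' `pos`, `ref`, `alt`) onto the parent sequence; the result reproduces
#' the accession exactly.
#'
#' @param parent parent genome sequence (character scalar or
#'   [QuadripartiteGenome]).
#' @param log mutation log data.frame.
#' @return mutated sequence (character scalar).
#' @export
applyMutationLog <- function(parent, log) {
    if (is(parent, "QuadripartiteGenome")) parent <- parent@sequence
    if (!nrow(log)) return(parent)
    log <- log[order(log$pos, decreasing = TRUE), , drop = FALSE]
    L <- nchar(parent)
    for (i in seq_len(nrow(log))) {
        p <- log$pos[i]; ref <- log$ref[i]; alt <- log$alt[i]
        if (substr(parent, p, p + nchar(ref) - 1L) != ref)
            csStop("ref_mismatch", sprintf(
                "log ref '%s' does not match parent at %d", ref, p))
        parent <- paste0(substr(parent, 1L, p - 1L), alt,
                         substr(parent, p + nchar(ref), L))
        L <- nchar(parent)
    }
    parent
}

#' Simulate paired-end shotgun reads with nuclear background
#'
#' Samples 400-bp-insert style read pairs from a circular chloroplast
#' genome at high coverage plus an i.i.d. random nuclear background at
#' low coverage, mimicking whole-genome shotgun data in which the
#' plastome is strongly over-represented. Fragments from the chloroplast
#' are drawn on the circle, so some pairs span the origin. Base errors
#' are uniform substitutions. Every read pair carries an origin label.
#'
#' @param genome chloroplast genome (character scalar or
#'   [QuadripartiteGenome]).
#' @param chloroCoverage chloroplast fold coverage (> 0).
#' @param nuclearLen length of the simulated nuclear background (bp);
#'   0 disables it.
#' @param nuclearCoverage nuclear fold coverage.
#' @param readLen read length in bp.
#' @param insertMean,insertSd fragment (insert) size distribution.
#' @param errorRate per-base substitution error rate.
#' @param qualityProfile "constant" (Q `q` everywhere) or "decay"
#'   (linear from `q` to `q - 10` along the read).
#' @param q base quality of the profile.
#' @param seed integer seed; identical seeds give byte-identical reads.
#' @return list with `reads` (a [PairedReads]), `labels` (data.frame
#'   `id`, `origin`, `start`, `fragLen`, `spansOrigin`) and
#'   `nuclearSequence`.
#' @export
simulateReads <- function(genome, chloroCoverage = 100,
                          nuclearLen = 1e6L, nuclearCoverage = 1,
                          readLen = 100L, insertMean = 400,
                          insertSd = 40, errorRate = 0.01,
                          qualityProfile = c("constant", "decay"),
                          q = 35L, seed = 1L) {
    if (is(genome, "QuadripartiteGenome")) genome <- genome@sequence
    qualityProfile <- match.arg(qualityProfile)
    if (chloroCoverage <= 0)
        csStop("invalid_parameter", "chloroCoverage must be > 0")
    if (readLen > insertMean)
        csStop("invalid_parameter", "readLen exceeds insertMean")
    if (insertMean < 2 * readLen)
        csWarn("short_insert",
               "insertMean < 2*readLen: mates will overlap")
    set.seed(seed)
    L <- nchar(genome)

    sampleFrom <- function(seqStr, nPairs, circular, prefix) {
        sl <- nchar(seqStr)
        frag <- pmin(pmax(round(rnorm(nPairs, insertMean, insertSd)),
                          readLen), sl)
        if (circular) {
            start <- sample.int(sl, nPairs, replace = TRUE)
            doubled <- paste0(seqStr, substr(seqStr, 1L, max(frag)))
            frags <- substring(doubled, start, start + frag - 1L)
        } else {
            start <- 1L + floor(runif(nPairs) * (sl - frag + 1))
            frags <- substring(seqStr, start, start + frag - 1L)
        }
        r1 <- substr(frags, 1L, readLen)
        r2 <- revComp(substring(frags, frag - readLen + 1L, frag))
        list(id = sprintf("%s%06d", prefix, seq_len(nPairs)),
             r1 = r1, r2 = r2, start = start, frag = frag)
    }

    injectErrors <- function(reads) {
        if (errorRate <= 0) return(reads)
        nerr <- rbinom(length(reads), nchar(reads), errorRate)
        idx <- which(nerr > 0)
        bases <- c("A", "C", "G", "T")
        for (i in idx) {
            pos <- sample.int(nchar(reads[i]), nerr[i])
            for (p in pos) {
                old <- substr(reads[i], p, p)
                substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
            }
        }
        reads
    }

    nChloro <- round(chloroCoverage * L / (2 * readLen))
    cp <- sampleFrom(genome, nChloro, circular = TRUE, prefix = "cp_")

    nuclear <- ""
    np <- NULL
    if (nuclearLen > 0 && nuclearCoverage > 0) {
        nuclear <- randomDNA(nuclearLen, 0.36)
        nNuc <- round(nuclearCoverage * nuclearLen / (2 * readLen))
        if (nNuc > 0)
            np <- sampleFrom(nuclear, nNuc, circular = FALSE,
                             prefix = "nu_")
    }

    id <- c(cp$id, np$id)
    seq1 <- injectErrors(c(cp$r1, np$r1))
    seq2 <- injectErrors(c(cp$r2, np$r2))

    qmax <- q
    qualStr <- if (qualityProfile == "constant") {
        strrep(intToUtf8(qmax + 33L), readLen)
    } else {
        qs <- round(seq(qmax, qmax - 10L, length.out = readLen))
        intToUtf8(qs + 33L, multiple = FALSE)
    }
    quals <- rep(qualStr, length(id))

    labels <- data.frame(
        id = id,
        origin = rep(c("chloroplast", "nuclear"),
                     c(length(cp$id), length(np$id))),
        start = c(cp$start, np$start),
        fragLen = c(cp$frag, np$frag),
        stringsAsFactors = FALSE)
    labels$spansOrigin <- labels$origin == "chloroplast" &
        (labels$start + labels$fragLen - 1L) > L

    list(reads = new("PairedReads", id = id, seq1 = seq1, seq2 = seq2,
                     qual1 = quals, qual2 = quals),
         labels = labels, nuclearSequence = nuclear)
}

#' Write a mutation log as TSV
#' @param log mutation log data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMutationLog <- function(log, path) {
    write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a mutation log TSV
#' @param path path written by [writeMutationLog()].
#' @return data.frame.
#' @export
readMutationLog <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
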