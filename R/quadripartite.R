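# quadripartite structure: IR detection, canonical rotation/orientation,
# genome equivalence, anchor chains, region slicing

#' Locate the inverted repeat pair of a circular sequence
#'
#' Finds the longest pair of disjoint spans whose sequences are exact
#' reverse complements, seeded at shared k-mers between the sequence and
#' its reverse complement and extended maximally. The longer inter-IR
#' arc is labelled LSC, the shorter SSC; IRa is the copy whose first
#' base follows the LSC going clockwise. If no repeat is found on the
#' linear cut, the search is repeated on a half-rotation so IRs spanning
#' the origin are still detected.
#'
#' @param x circular genome sequence (character scalar) or
#'   [QuadripartiteGenome].
#' @param minIrLen minimum IR length per copy (default 1000 bp).
#' @param seedK seed word size for the repeat search.
#' @return a [RegionMap] on the input sequence's coordinates.
#' @export
findInvertedRepeat <- function(x, minIrLen = 1000L, seedK = 21L) {
    seq <- if (is(x, "QuadripartiteGenome")) x@sequence else
        as.character(x)
    L <- nchar(seq)
    if (L < 4L * minIrLen)
        csWarn("short_sequence",
               "sequence shorter than 4 * minIrLen")
    pick <- function(m) {
        m <- m[m$length >= minIrLen, , drop = FALSE]
        if (nrow(m)) m[1, , drop = FALSE] else NULL
    }
    hit <- pick(cpp_inverted_matches(seq, seedK))
    shift <- 0L
    if (is.null(hit) && L >= 2L) {
        # IR may straddle the origin of the linear cut
        shift <- L %/% 2L
        hit <- pick(cpp_inverted_matches(rotateSeq(seq, shift + 1L),
                                         seedK))
    }
    if (is.null(hit))
        csStop("no_ir_found",
               sprintf("no inverted repeat of >= %d bp", minIrLen))
    unrot <- function(p, sh) ((p - 1L + sh) %% L) + 1L
    # the linear cut may truncate an IR copy; re-rotate so the cut sits
    # in the middle of the longer inter-IR arc and detect again exactly
    {
        e1o <- unrot(hit$end1, shift); s2o <- unrot(hit$start2, shift)
        e2o <- unrot(hit$end2, shift); s1o <- unrot(hit$start1, shift)
        arcA <- (s2o - e1o - 1L) %% L
        arcB <- (s1o - e2o - 1L) %% L
        mid <- if (arcA >= arcB)
            unrot(((arcA + 1L) %/% 2L), e1o) else
            unrot(((arcB + 1L) %/% 2L), e2o)
        shift2 <- mid - 1L
        hit2 <- pick(cpp_inverted_matches(rotateSeq(seq, shift2 + 1L),
                                          seedK))
        if (!is.null(hit2) && hit2$length >= hit$length) {
            hit <- hit2
            shift <- shift2
        }
    }
    s1 <- unrot(hit$start1, shift); e1 <- unrot(hit$end1, shift)
    s2 <- unrot(hit$start2, shift); e2 <- unrot(hit$end2, shift)
    irLen <- hit$length

    arcAlen <- (s2 - e1 - 1L) %% L   # arc after copy 1
    arcBlen <- (s1 - e2 - 1L) %% L   # arc after copy 2
    if (arcAlen == 0L || arcBlen == 0L)
        csStop("no_ir_found",
               "inverted repeat leaves no single-copy arc")
    arcA <- c(start = (e1 %% L) + 1L, end = ((s2 - 2L) %% L) + 1L)
    arcB <- c(start = (e2 %% L) + 1L, end = ((s1 - 2L) %% L) + 1L)
    if (arcAlen == arcBlen)
        csStop("no_ir_found", "inter-IR arcs have equal length")
    if (arcAlen > arcBlen) {
        lsc <- arcA; ssc <- arcB
        ira <- c(start = s2, end = e2)  # follows the LSC arc
        irb <- c(start = s1, end = e1)
    } else {
        lsc <- arcB; ssc <- arcA
        ira <- c(start = s1, end = e1)
        irb <- c(start = s2, end = e2)
    }
    new("RegionMap",
        spans = data.frame(
            region = c("LSC", "IRa", "SSC", "IRb"),
            start = as.integer(c(lsc["start"], ira["start"],
                                 ssc["start"], irb["start"])),
            end = as.integer(c(lsc["end"], ira["end"],
                               ssc["end"], irb["end"])),
            length = as.integer(c(max(arcAlen, arcBlen), irLen,
                                  min(arcAlen, arcBlen), irLen)),
            stringsAsFactors = FALSE),
        totalLength = as.integer(L))
}

#' Canonicalize a quadripartite genome
#'
#' Rotates and, if needed, reflects a circular quadripartite sequence to
#' the canonical form: starting at LSC base 1 in the order LSC, IRa,
#' SSC, IRb. Of the two strand readings the lexicographically smaller
#' canonical sequence is chosen, so the result is unique for all
#' rotations and reflections of the same circle.
#'
#' @param x genome sequence (character scalar) or [QuadripartiteGenome].
#' @param map a [RegionMap] for `x`; found with [findInvertedRepeat()]
#'   when missing.
#' @param provenance provenance tag for the result.
#' @param ... passed to [findInvertedRepeat()] when `map` is missing.
#' @return a canonical [QuadripartiteGenome].
#' @export
canonicalizeGenome <- function(x, map = NULL,
                               provenance = "assembled", ...) {
    seq <- if (is(x, "QuadripartiteGenome")) x@sequence else
        as.character(x)
    if (is.null(map)) {
        map <- if (is(x, "QuadripartiteGenome")) x@regionMap else
            findInvertedRepeat(seq, ...)
    }
    if (is(x, "QuadripartiteGenome") && provenance == "assembled")
        provenance <- x@provenance
    sp <- map@spans
    L <- map@totalLength
    if (nchar(seq) != L)
        csStop("invalid_region_map",
               "region map total length differs from sequence length")
    get <- function(r) {
        i <- match(r, sp$region)
        circularSubstr(seq, sp$start[i], sp$end[i])
    }
    lsc <- get("LSC"); ssc <- get("SSC")
    # region following the LSC clockwise must be an IR copy
    lscEnd <- sp$end[sp$region == "LSC"]
    nextStart <- (lscEnd %% L) + 1L
    firstIr <- sp$region[sp$start == nextStart]
    if (!length(firstIr) || !firstIr %in% c("IRa", "IRb"))
        csStop("invalid_region_map",
               "LSC is not followed by an IR copy")
    ir1 <- get(firstIr)
    ir2 <- get(setdiff(c("IRa", "IRb"), firstIr))
    if (!identical(ir1, revComp(ir2)))
        csStop("invalid_region_map",
               "IR copies are not exact reverse complements")
    cand1 <- paste0(lsc, ir1, ssc, ir2)
    # reading the circle on the other strand, rotated back to LSC start
    cand2 <- paste0(revComp(lsc), ir1, revComp(ssc), ir2)
    canon <- if (cand1 <= cand2) cand1 else cand2
    new("QuadripartiteGenome", sequence = canon,
        regionMap = regionMapFromLengths(nchar(lsc), nchar(ir1),
                                         nchar(ssc)),
        provenance = provenance)
}

#' Flip the SSC orientation of a canonical genome
#'
#' Returns the orientation isomer in which the SSC is
#' reverse-complemented in place; both isomers coexist in plastid
#' preparations.
#'
#' @param genome a canonical [QuadripartiteGenome].
#' @return a [QuadripartiteGenome] with the SSC flipped.
#' @export
sscFlip <- function(genome) {
    stopifnot(is(genome, "QuadripartiteGenome"))
    lsc <- regionSequence(genome, "LSC")
    ira <- regionSequence(genome, "IRa")
    ssc <- regionSequence(genome, "SSC")
    irb <- regionSequence(genome, "IRb")
    new("QuadripartiteGenome",
        sequence = paste0(lsc, ira, revComp(ssc), irb),
        regionMap = genome@regionMap, provenance = genome@provenance)
}

#' Test whether two circular quadripartite genomes are equivalent
#'
#' Two genomes are equivalent when their canonical forms are identical,
#' i.e. they are the same circle up to rotation and strand. With
#' `allowSscFlip = TRUE` (default) the SSC orientation isomer is also
#' accepted as the same genome.
#'
#' @param a,b genome sequences (character) or [QuadripartiteGenome]s.
#' @param allowSscFlip treat SSC orientation isomers as equivalent.
#' @param ... passed to [findInvertedRepeat()] for plain sequences.
#' @return list with `equivalent` (logical), `sscFlipped` (logical:
#'   equivalence required the flip), `mismatches` (Hamming distance of
#'   canonical forms when equal length, else NA), `lengthA`, `lengthB`
#'   and `reason` for canonicalization failures.
#' @export
genomesEquivalent <- function(a, b, allowSscFlip = TRUE, ...) {
    canon <- function(x) tryCatch(canonicalizeGenome(x, ...),
                                  error = function(e) e)
    ca <- canon(a); cb <- canon(b)
    if (is(ca, "error") || is(cb, "error")) {
        bad <- if (is(ca, "error")) ca else cb
        return(list(equivalent = FALSE, sscFlipped = FALSE,
                    mismatches = NA_integer_,
                    lengthA = NA_integer_, lengthB = NA_integer_,
                    reason = conditionMessage(bad)))
    }
    sa <- ca@sequence; sb <- cb@sequence
    mm <- if (nchar(sa) == nchar(sb)) hammingDist(sa, sb) else
        NA_integer_
    if (identical(sa, sb))
        return(list(equivalent = TRUE, sscFlipped = FALSE,
                    mismatches = 0L, lengthA = nchar(sa),
                    lengthB = nchar(sb), reason = NA_character_))
    if (allowSscFlip) {
        cbF <- canonicalizeGenome(sscFlip(cb))
        if (identical(sa, cbF@sequence))
            return(list(equivalent = TRUE, sscFlipped = TRUE,
                        mismatches = 0L, lengthA = nchar(sa),
                        lengthB = nchar(sb), reason = NA_character_))
        if (nchar(sa) == nchar(cbF@sequence)) {
            mmF <- hammingDist(sa, cbF@sequence)
            if (is.na(mm) || mmF < mm) mm <- mmF
        }
    }
    list(equivalent = FALSE, sscFlipped = FALSE,
         mismatches = if (is.finite(mm)) as.integer(mm) else
             NA_integer_,
         lengthA = nchar(sa), lengthB = nchar(sb),
         reason = NA_character_)
}

#' Restore the quadripartite circle from a collapsed assembly
#'
#' In a de Bruijn assembly of a plastome the two IR copies collapse into
#' one unitig at roughly twice single-copy coverage, flanked by the LSC
#' and SSC arc unitigs. Using the coverage evidence, this stitches the
#' three scaffolds back into the full circle LSC + IR + SSC + rc(IR)
#' via their exact (k-1)-base overlaps. A single circular scaffold is
#' returned as-is; a single linear scaffold with matching ends is
#' circularized.
#'
#' @param assembly an [Assembly] (typically after gap filling).
#' @return the restored circular sequence (character scalar).
#' @export
restoreQuadripartite <- function(assembly) {
    stopifnot(is(assembly, "Assembly"))
    k1 <- assembly@k - 1L
    scafs <- assembly@scaffolds
    if (length(scafs) == 1L) {
        s <- scafs[1]
        if (assembly@meta$circular[1]) return(s)
        if (nchar(s) > 2L * k1 &&
            substr(s, nchar(s) - k1 + 1L, nchar(s)) ==
            substr(s, 1L, k1))
            return(substr(s, 1L, nchar(s) - k1))
        return(s)
    }
    if (length(scafs) != 3L)
        csStop("unresolved_quadripartite", sprintf(
            "cannot resolve quadripartite structure from %d scaffolds",
            length(scafs)))
    covs <- assembly@meta$meanCov
    irIdx <- which.max(covs)
    rest <- setdiff(seq_along(scafs), irIdx)
    rest <- rest[order(-nchar(scafs[rest]))]
    A <- scafs[rest[1]]; B <- scafs[rest[2]]; R <- scafs[irIdx]
    sfx <- function(s) substr(s, nchar(s) - k1 + 1L, nchar(s))
    pfx <- function(s) substr(s, 1L, k1)
    for (a in c(A, revComp(A))) for (r in c(R, revComp(R)))
        for (b in c(B, revComp(B))) {
            rr <- revComp(r)
            if (sfx(a) == pfx(r) && sfx(r) == pfx(b) &&
                sfx(b) == pfx(rr) && sfx(rr) == pfx(a)) {
                circle <- paste0(a,
                                 substr(r, k1 + 1L, nchar(r)),
                                 substr(b, k1 + 1L, nchar(b)),
                                 substr(rr, k1 + 1L, nchar(rr)))
                return(substr(circle, 1L, nchar(circle) - k1))
            }
        }
    csStop("unresolved_quadripartite",
           "scaffold overlaps do not close the quadripartite circle")
}

#' Build a collinear anchor chain between two genomes
#'
#' Anchors are maximal exact matches seeded at k-mers unique in both
#' sequences; the chain is the highest-scoring subset with strictly
#' increasing, non-overlapping target spans and non-overlapping query
#' spans (total anchored length maximized). Inverted segments appear as
#' minus-strand anchors. The chain is the backbone of a MUMmer-style
#' dot plot.
#'
#' @param query,target sequences (character scalars or
#'   [QuadripartiteGenome]s).
#' @param anchorK seed word size.
#' @return an [AnchorChain].
#' @export
buildAnchorChain <- function(query, target, anchorK = 21L) {
    q <- if (is(query, "QuadripartiteGenome")) query@sequence else
        as.character(query)
    t <- if (is(target, "QuadripartiteGenome")) target@sequence else
        as.character(target)
    if (!nchar(q) || !nchar(t))
        csStop("empty_chain", "empty input sequence")
    a <- cpp_anchors(q, t, as.integer(anchorK))
    if (!nrow(a))
        csStop("empty_chain", "no unique anchors between the genomes")
    a <- a[order(a$tstart, a$tend), , drop = FALSE]
    n <- nrow(a)
    len <- a$qend - a$qstart + 1L
    dp <- as.numeric(len)
    prev <- rep(NA_integer_, n)
    # maximal extension lets neighbouring anchors overlap by a few
    # bases around an indel in repeat context; allow overlaps below the
    # seed size here and trim them after chain selection
    maxOv <- as.integer(anchorK) - 1L
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            if (a$tend[j] - a$tstart[i] >= maxOv) next
            if (a$qend[j] - a$qstart[i] >= maxOv) next
            if (a$tstart[j] >= a$tstart[i]) next
            if (a$qstart[j] >= a$qstart[i]) next
            if (dp[j] + len[i] > dp[i]) {
                dp[i] <- dp[j] + len[i]
                prev[i] <- j
            }
        }
    }
    i <- which.max(dp)
    keep <- integer(0)
    while (!is.na(i)) { keep <- c(i, keep); i <- prev[i] }
    a <- a[keep, , drop = FALSE]
    if (nrow(a) > 1) {
        for (i in 2:nrow(a)) {
            qOv <- max(0L, a$qend[i - 1L] - a$qstart[i] + 1L)
            tOv <- max(0L, a$tend[i - 1L] - a$tstart[i] + 1L)
            if (a$strand[i] == "+") {
                d <- max(qOv, tOv)
                a$qstart[i] <- a$qstart[i] + d
                a$tstart[i] <- a$tstart[i] + d
            } else {
                # on '-', query start pairs with target end and vice versa
                a$qstart[i] <- a$qstart[i] + qOv
                a$tend[i] <- a$tend[i] - qOv
                a$tstart[i] <- a$tstart[i] + tOv
                a$qend[i] <- a$qend[i] - tOv
            }
        }
        a <- a[a$qend >= a$qstart & a$tend >= a$tstart, , drop = FALSE]
    }
    a$length <- a$qend - a$qstart + 1L
    rownames(a) <- NULL
    new("AnchorChain", anchors = a, qlen = nchar(q), tlen = nchar(t))
}

#' Write an anchor chain as dot-plot TSV
#' @param chain an [AnchorChain].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnchorChain <- function(chain, path) {
    write.table(chainAnchors(chain), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Slice a canonical genome into its region sequences
#'
#' @param genome a canonical [QuadripartiteGenome].
#' @return named list with `LSC`, `SSC`, `IRa`, `IRb`, `LSC_SSC` (the
#'   concatenation used for the single-copy dataset split) and `whole`.
#' @export
sliceRegions <- function(genome) {
    stopifnot(is(genome, "QuadripartiteGenome"))
    lsc <- regionSequence(genome, "LSC")
    ssc <- regionSequence(genome, "SSC")
    list(LSC = lsc, SSC = ssc,
         IRa = regionSequence(genome, "IRa"),
         IRb = regionSequence(genome, "IRb"),
         LSC_SSC = paste0(lsc, ssc),
         whole = genome@sequence)
}

#' Write a region map as BED-like TSV
#'
#' Coordinates are 1-based inclusive; a span may wrap the circular
#' origin (start > end).
#'
#' @param map a [RegionMap] or [QuadripartiteGenome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionMap <- function(map, path) {
    if (is(map, "QuadripartiteGenome")) map <- map@regionMap
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# region spans, 1-based inclusive, circular ",
                      "coordinates (start > end wraps); total length ",
                      map@totalLength), con)
    utils::write.table(map@spans, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
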