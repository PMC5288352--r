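# variant calling between collinear genomes, normalization,
# multi-sample merging, density reports and window tracks

#' Classify an SNV as transition or transversion
#'
#' A<->G and C<->T exchanges (purine<->purine, pyrimidine<->pyrimidine)
#' are transitions; every other base exchange is a transversion.
#'
#' @param ref,alt single reference and alternate bases.
#' @return "transition" or "transversion" (vectorized).
#' @export
classifySnv <- function(ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    bad <- !(ref %in% c("A", "C", "G", "T")) |
        !(alt %in% c("A", "C", "G", "T")) | ref == alt
    if (any(bad))
        csStop("invalid_variant",
               "ref/alt must be distinct bases in {A,C,G,T}")
    ifelse((ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
           (ref == "C" & alt == "T") | (ref == "T" & alt == "C"),
           "transition", "transversion")
}

variantClassOf <- function(ref, alt) {
    ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
           ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

# trim shared trailing/leading allele bases without reference context
# (minimal representation); left shifting through repeats needs the
# reference and lives in normalizeVariant
trimAllelePair <- function(pos, ref, alt) {
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' Left-normalize a variant against its reference
#'
#' Shifts InDels left through repeat context to the smallest position
#' with the identical haplotype effect, using the VCF anchor-base
#' convention; SNVs are returned unchanged. Idempotent.
#'
#' @param variant list or one-row data.frame with `pos`, `ref`, `alt`.
#' @param reference reference sequence (character scalar).
#' @return list with normalized `pos`, `ref`, `alt` and `class`.
#' @export
normalizeVariant <- function(variant, reference) {
    pos <- as.integer(variant$pos)
    ref <- as.character(variant$ref)
    alt <- as.character(variant$alt)
    if (substr(reference, pos, pos + nchar(ref) - 1L) != ref)
        csStop("ref_mismatch", sprintf(
            "variant ref '%s' does not match reference at %d", ref, pos))
    lastCh <- function(s) substr(s, nchar(s), nchar(s))
    repeat {
        if (nchar(ref) >= 1L && nchar(alt) >= 1L &&
            lastCh(ref) == lastCh(alt) &&
            (nchar(ref) > 1L || nchar(alt) > 1L)) {
            # chopping would empty an allele only if we can extend left
            if ((nchar(ref) == 1L || nchar(alt) == 1L) && pos <= 1L)
                break
            ref <- substr(ref, 1L, nchar(ref) - 1L)
            alt <- substr(alt, 1L, nchar(alt) - 1L)
            if (nchar(ref) == 0L || nchar(alt) == 0L) {
                pos <- pos - 1L
                b <- substr(reference, pos, pos)
                ref <- paste0(b, ref)
                alt <- paste0(b, alt)
            }
        } else break
    }
    # drop shared leading bases beyond the single anchor
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    list(pos = pos, ref = ref, alt = alt,
         class = variantClassOf(ref, alt))
}

# align two segments globally (affine gaps) and emit raw variants on
# reference coordinates; refStart is the reference position of the
# segment's first base, anchorBase/anchorPos give the base left of the
# segment for indel anchoring
alignSegment <- function(refSeg, smpSeg, refStart, reference) {
    if (!nchar(refSeg) && !nchar(smpSeg)) return(NULL)
    anchorPos <- refStart - 1L
    if (!nchar(refSeg) || !nchar(smpSeg)) {
        # pure insertion/deletion between anchors
        if (anchorPos < 1L) return(NULL)
        b <- substr(reference, anchorPos, anchorPos)
        return(data.frame(
            pos = anchorPos, ref = paste0(b, refSeg),
            alt = paste0(b, smpSeg), stringsAsFactors = FALSE))
    }
    al <- Biostrings::pairwiseAlignment(
        pattern = smpSeg, subject = refSeg, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2),
        gapOpening = 4, gapExtension = 1)
    ar <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    out <- list()
    refPos <- refStart - 1L
    i <- 1L
    n <- length(ar)
    while (i <= n) {
        if (ar[i] != "-" && as_[i] != "-") {
            refPos <- refPos + 1L
            if (ar[i] != as_[i])
                out[[length(out) + 1L]] <- data.frame(
                    pos = refPos, ref = ar[i], alt = as_[i],
                    stringsAsFactors = FALSE)
            i <- i + 1L
        } else {
            j <- i
            while (j <= n && (ar[j] == "-" || as_[j] == "-") &&
                   (ar[j] == "-") == (ar[i] == "-")) j <- j + 1L
            run <- i:(j - 1L)
            if (ar[i] == "-") { # insertion in sample
                insSeq <- paste(as_[run], collapse = "")
                if (refPos >= 1L) {
                    b <- substr(reference, refPos, refPos)
                    out[[length(out) + 1L]] <- data.frame(
                        pos = refPos, ref = b,
                        alt = paste0(b, insSeq),
                        stringsAsFactors = FALSE)
                }
            } else {            # deletion in sample
                delSeq <- paste(ar[run], collapse = "")
                if (refPos >= 1L) {
                    b <- substr(reference, refPos, refPos)
                    out[[length(out) + 1L]] <- data.frame(
                        pos = refPos, ref = paste0(b, delSeq),
                        alt = b, stringsAsFactors = FALSE)
                }
                refPos <- refPos + length(run)
            }
            i <- j
        }
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
}

#' Call variants between a sample genome and a reference
#'
#' Verifies collinearity through a unique-anchor chain (aborting when
#' the chain covers less than `minChainCoverage` of the reference),
#' globally aligns the inter-anchor segments with affine gap penalties
#' (match +1, mismatch -2, gap open -4, gap extend -1) and converts the
#' alignment columns into left-normalized variants on reference
#' coordinates.
#'
#' @param sample,reference genome sequences (character scalars or
#'   [QuadripartiteGenome]s).
#' @param anchorK anchor seed word size.
#' @param minChainCoverage minimum fraction of the reference covered by
#'   the plus-strand anchor chain.
#' @param refId reference identifier recorded on the output.
#' @return data.frame with `pos`, `ref`, `alt`, `class` (SNV/INS/DEL),
#'   `tstv` (for SNVs), `indelLen` (signed; 0 for SNVs); attribute
#'   `refId`.
#' @export
callVariants <- function(sample, reference, anchorK = 21L,
                         minChainCoverage = 0.9,
                         refId = "reference") {
    smp <- if (is(sample, "QuadripartiteGenome")) sample@sequence else
        as.character(sample)
    ref <- if (is(reference, "QuadripartiteGenome"))
        reference@sequence else as.character(reference)
    chain <- buildAnchorChain(smp, ref, anchorK)
    a <- chainAnchors(chain)
    a <- a[a$strand == "+", , drop = FALSE]
    cov <- if (nrow(a)) sum(a$tend - a$tstart + 1) / nchar(ref) else 0
    if (cov < minChainCoverage)
        csStop("not_collinear", sprintf(
            "anchor chain covers %.1f%% of the reference (< %.0f%%)",
            100 * cov, 100 * minChainCoverage), coverage = cov)
    segs <- list()
    # leading, inter-anchor and trailing segments
    bounds <- rbind(
        data.frame(rs = 1L, re = a$tstart[1] - 1L,
                   qs = 1L, qe = a$qstart[1] - 1L),
        if (nrow(a) > 1) data.frame(
            rs = a$tend[-nrow(a)] + 1L, re = a$tstart[-1] - 1L,
            qs = a$qend[-nrow(a)] + 1L, qe = a$qstart[-1] - 1L),
        data.frame(rs = a$tend[nrow(a)] + 1L, re = nchar(ref),
                   qs = a$qend[nrow(a)] + 1L, qe = nchar(smp)))
    raw <- list()
    for (i in seq_len(nrow(bounds))) {
        rs <- bounds$rs[i]; re <- bounds$re[i]
        qs <- bounds$qs[i]; qe <- bounds$qe[i]
        refSeg <- if (re >= rs) substr(ref, rs, re) else ""
        smpSeg <- if (qe >= qs) substr(smp, qs, qe) else ""
        v <- alignSegment(refSeg, smpSeg, rs, ref)
        if (!is.null(v)) raw[[length(raw) + 1L]] <- v
    }
    if (!length(raw)) {
        out <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), class = character(0),
                          tstv = character(0), indelLen = integer(0),
                          stringsAsFactors = FALSE)
        attr(out, "refId") <- refId
        return(out)
    }
    raw <- do.call(rbind, raw)
    norm <- lapply(seq_len(nrow(raw)), function(i)
        normalizeVariant(raw[i, ], ref))
    out <- data.frame(
        pos = vapply(norm, `[[`, integer(1), "pos"),
        ref = vapply(norm, `[[`, character(1), "ref"),
        alt = vapply(norm, `[[`, character(1), "alt"),
        class = vapply(norm, `[[`, character(1), "class"),
        stringsAsFactors = FALSE)
    out <- out[!duplicated(out[, c("pos", "ref", "alt")]), ,
               drop = FALSE]
    out <- out[order(out$pos), , drop = FALSE]
    out$tstv <- NA_character_
    isSnv <- out$class == "SNV"
    if (any(isSnv))
        out$tstv[isSnv] <- classifySnv(out$ref[isSnv], out$alt[isSnv])
    out$indelLen <- nchar(out$alt) - nchar(out$ref)
    rownames(out) <- NULL
    attr(out, "refId") <- refId
    out
}

#' Merge per-sample variant calls into a multi-sample table
#'
#' Groups normalized variants by position and class family (SNV versus
#' InDel), recording the union of alternate alleles and per-sample
#' presence. A position is flagged triallelic when two or more distinct
#' alternate alleles are observed across samples.
#'
#' @param calls named list of per-sample call data.frames (from
#'   [callVariants()] or [readVcfTable()]).
#' @param refId reference identifier; when the call sets carry a
#'   `refId` attribute it must agree.
#' @param refLength reference length in bp.
#' @return a [VariantTable].
#' @export
mergeSamples <- function(calls, refId = "reference", refLength) {
    stopifnot(is.list(calls), length(calls) > 0)
    if (is.null(names(calls)))
        names(calls) <- paste0("sample", seq_along(calls))
    for (nm in names(calls)) {
        rid <- attr(calls[[nm]], "refId")
        if (!is.null(rid) && rid != refId)
            csStop("reference_mismatch", sprintf(
                "sample '%s' was called against '%s', not '%s'",
                nm, rid, refId))
    }
    ev <- do.call(rbind, lapply(names(calls), function(nm) {
        df <- calls[[nm]]
        if (!nrow(df)) return(NULL)
        data.frame(sample = nm, pos = df$pos, ref = df$ref,
                   alt = df$alt, class = df$class,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(ev))
        ev <- data.frame(sample = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         class = character(0), stringsAsFactors = FALSE)
    ev$classGroup <- ifelse(ev$class == "SNV", "SNV", "InDel")
    if (nrow(ev)) {
        key <- paste(ev$pos, ev$classGroup)
        grp <- split(seq_len(nrow(ev)), key)
        calls2 <- do.call(rbind, lapply(grp, function(idx) {
            sub <- ev[idx, ]
            alleles <- unique(paste0(sub$ref, ">", sub$alt))
            data.frame(
                pos = sub$pos[1], class = sub$classGroup[1],
                ref = sub$ref[which.max(nchar(sub$ref))],
                alts = paste(sort(unique(sub$alt)), collapse = ","),
                nAlt = length(alleles),
                triallelic = length(alleles) >= 2L,
                nSamples = length(unique(sub$sample)),
                stringsAsFactors = FALSE)
        }))
        calls2 <- calls2[order(calls2$pos, calls2$class), ,
                         drop = FALSE]
        rownames(calls2) <- NULL
    } else {
        calls2 <- data.frame(pos = integer(0), class = character(0),
                             ref = character(0), alts = character(0),
                             nAlt = integer(0), triallelic = logical(0),
                             nSamples = integer(0),
                             stringsAsFactors = FALSE)
    }
    ev$classGroup <- NULL
    new("VariantTable", refId = refId,
        refLength = as.integer(refLength),
        samples = names(calls), events = ev, calls = calls2)
}

#' Build the exon/intron/intergenic partition from gene annotation
#'
#' Exon is the union of exon spans; intron is gene minus exon;
#' intergenic is the complement. The three categories are disjoint and
#' exactly cover the reference.
#'
#' @param annotation data.frame with columns `type` ("gene"/"exon"),
#'   `start`, `end`, `gene` (gene id), a GFF3 file path, or a GRanges
#'   (gene/exon in its `type` column).
#' @param refLength reference length in bp.
#' @return a [FeaturePartition].
#' @export
buildFeaturePartition <- function(annotation, refLength) {
    refLength <- as.integer(refLength)
    if (is.character(annotation) && length(annotation) == 1L) {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            csStop("invalid_annotation",
                   "reading GFF3 requires the rtracklayer package")
        gr <- as.data.frame(rtracklayer::import(annotation))
        annotation <- data.frame(
            type = as.character(gr$type),
            start = gr$start,
            end = gr$end,
            gene = if (!is.null(gr$Parent))
                as.character(gr$Parent) else
                as.character(seq_len(nrow(gr))),
            stringsAsFactors = FALSE)
    }
    ann <- as.data.frame(annotation)
    genes <- ann[tolower(ann$type) == "gene", , drop = FALSE]
    exons <- ann[tolower(ann$type) == "exon", , drop = FALSE]
    geneR <- if (nrow(genes))
        IRanges::reduce(IRanges::IRanges(genes$start, genes$end)) else
        IRanges::IRanges()
    exonR <- if (nrow(exons))
        IRanges::reduce(IRanges::IRanges(exons$start, exons$end)) else
        IRanges::IRanges()
    if (length(exonR)) {
        outside <- IRanges::setdiff(exonR, geneR)
        if (sum(IRanges::width(outside)) > 0)
            csStop("invalid_annotation",
                   "exon span outside any gene")
    }
    all <- IRanges::IRanges(1L, refLength)
    intronR <- IRanges::setdiff(geneR, exonR)
    intergenicR <- IRanges::setdiff(all, geneR)
    new("FeaturePartition", exon = exonR, intron = intronR,
        intergenic = intergenicR, refLength = refLength)
}

# per-kb density with the report's display rounding: one decimal at
# >= 0.1 (and exact zero), two decimals below
perKbDensity <- function(count, spanBp) {
    count * 1000 / spanBp
}

displayDensity <- function(d) {
    ifelse(d >= 0.1 | d == 0, round(d, 1), round(d, 2))
}

regionOfPositions <- function(pos, map) {
    sp <- map@spans
    L <- map@totalLength
    out <- rep(NA_character_, length(pos))
    for (i in seq_len(nrow(sp))) {
        s <- sp$start[i]; e <- sp$end[i]
        inSpan <- if (s <= e) pos >= s & pos <= e else
            pos >= s | pos <= e
        out[inSpan] <- sp$region[i]
    }
    out
}

#' Per-region and per-feature variant densities
#'
#' Counts variants per scope (whole genome; LSC, SSC, pooled IR; and,
#' with a [FeaturePartition], exon/intron/intergenic) for each variant
#' class and reports densities per kilobase (`density = count * 1000 /
#' span`). A variant belongs to the scope containing its normalized
#' 1-based position (the anchor base for InDels). The IR span pools
#' both copies.
#'
#' @param x a [VariantTable] or data.frame with `pos` and `class`.
#' @param map a [RegionMap] (optional).
#' @param features a [FeaturePartition] (optional).
#' @param refLength reference length; taken from `x` or `map` when
#'   missing.
#' @param classes variant class families to report.
#' @return data.frame with `scope`, `class`, `count`, `span`,
#'   `density` (full precision) and `display` (rounded like the report
#'   tables).
#' @export
densityReport <- function(x, map = NULL, features = NULL,
                          refLength = NULL,
                          classes = c("SNV", "InDel")) {
    df <- if (is(x, "VariantTable")) variantCalls(x) else
        as.data.frame(x)
    if (is.null(refLength)) {
        refLength <- if (is(x, "VariantTable")) x@refLength else
            if (!is.null(map)) map@totalLength else
                csStop("invalid_parameter", "refLength is required")
    }
    if (nrow(df) && !"class" %in% names(df))
        csStop("invalid_parameter", "x needs a class column")
    cls <- if (nrow(df))
        ifelse(df$class == "SNV", "SNV", "InDel") else character(0)
    rows <- list()
    addRow <- function(scope, class, count, span) {
        rows[[length(rows) + 1L]] <<- data.frame(
            scope = scope, class = class, count = count, span = span,
            density = perKbDensity(count, span),
            stringsAsFactors = FALSE)
    }
    for (cl in classes) {
        pos <- df$pos[cls == cl]
        addRow("whole", cl, length(pos), refLength)
        if (!is.null(map)) {
            reg <- regionOfPositions(pos, map)
            sp <- map@spans
            lscSpan <- sp$length[sp$region == "LSC"]
            sscSpan <- sp$length[sp$region == "SSC"]
            irSpan <- sum(sp$length[sp$region %in% c("IRa", "IRb")])
            addRow("LSC", cl, sum(reg == "LSC", na.rm = TRUE), lscSpan)
            addRow("SSC", cl, sum(reg == "SSC", na.rm = TRUE), sscSpan)
            addRow("IR", cl,
                   sum(reg %in% c("IRa", "IRb"), na.rm = TRUE), irSpan)
        }
        if (!is.null(features)) {
            posR <- IRanges::IRanges(pos, pos)
            cnt <- function(r) sum(IRanges::countOverlaps(posR, r) > 0)
            addRow("exon", cl, cnt(features@exon),
                   sum(IRanges::width(features@exon)))
            addRow("intron", cl, cnt(features@intron),
                   sum(IRanges::width(features@intron)))
            addRow("intergenic", cl, cnt(features@intergenic),
                   sum(IRanges::width(features@intergenic)))
        }
    }
    out <- do.call(rbind, rows)
    out$display <- displayDensity(out$density)
    out
}

#' Windowed variant counts along the reference
#'
#' Tiles non-overlapping windows from position 1 (the last partial
#' window keeps its true span) and counts variants per window by
#' normalized position.
#'
#' @param x a [VariantTable] or data.frame with `pos`.
#' @param window window size in bp (default 500).
#' @param refLength reference length; taken from a [VariantTable] when
#'   missing.
#' @return a [WindowTrack].
#' @export
windowDensity <- function(x, window = 500L, refLength = NULL) {
    if (window < 1L)
        csStop("invalid_parameter", "window must be >= 1")
    df <- if (is(x, "VariantTable")) variantCalls(x) else
        as.data.frame(x)
    if (is.null(refLength)) {
        if (is(x, "VariantTable")) refLength <- x@refLength else
            csStop("invalid_parameter", "refLength is required")
    }
    window <- as.integer(window)
    refLength <- as.integer(refLength)
    nWin <- ceiling(refLength / window)
    start <- (seq_len(nWin) - 1L) * window + 1L
    end <- pmin(start + window - 1L, refLength)
    idx <- (df$pos - 1L) %/% window + 1L
    count <- tabulate(idx, nbins = nWin)
    new("WindowTrack", window = window,
        track = data.frame(start = start, end = end, count = count),
        refLength = refLength)
}

#' Hotspot windows of a track
#'
#' Windows whose count exceeds the given quantile of all window counts
#' (the variation-hotspot convention used for the density maps).
#'
#' @param track a [WindowTrack].
#' @param prob quantile threshold (default 0.95).
#' @return data.frame of hotspot windows.
#' @export
hotspotWindows <- function(track, prob = 0.95) {
    stopifnot(is(track, "WindowTrack"))
    tr <- track@track
    thr <- quantile(tr$count, prob, names = FALSE)
    tr[tr$count > thr & tr$count > 0, , drop = FALSE]
}

#' Write a window track as TSV
#'
#' Spans are 1-based inclusive (bedgraph-style, but closed intervals).
#'
#' @param track a [WindowTrack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWindowTrack <- function(track, path) {
    write.table(windowCounts(track), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
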