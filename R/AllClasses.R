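# S4 classes for the central data containers

#' Paired-end reads
#'
#' Holds mate-paired reads with Phred+33 quality strings. Sequences are
#' stored as plain character vectors so the k-mer kernels can work on
#' them directly; use [readPairedFastq()] / [writePairedFastq()] for IO.
#'
#' @slot id read-pair identifiers.
#' @slot seq1,seq2 mate sequences.
#' @slot qual1,qual2 mate quality strings (Phred+33).
#' @export
setClass("PairedReads", representation(
    id = "character",
    seq1 = "character", seq2 = "character",
    qual1 = "character", qual2 = "character"
))

setValidity("PairedReads", function(object) {
    n <- length(object@id)
    if (any(lengths(list(object@seq1, object@seq2,
                         object@qual1, object@qual2)) != n))
        return("all slots must have equal length")
    if (any(nchar(object@seq1) != nchar(object@qual1)) ||
        any(nchar(object@seq2) != nchar(object@qual2)))
        return("sequence and quality lengths differ")
    TRUE
})

#' @describeIn PairedReads number of read pairs
#' @param x a `PairedReads` object.
#' @export
setMethod("length", "PairedReads", function(x) length(x@id))

#' @describeIn PairedReads subset read pairs
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PairedReads", function(x, i, j, ..., drop = TRUE) {
    new("PairedReads", id = x@id[i],
        seq1 = x@seq1[i], seq2 = x@seq2[i],
        qual1 = x@qual1[i], qual2 = x@qual2[i])
})

setMethod("show", "PairedReads", function(object) {
    cat("PairedReads with", length(object), "pairs\n")
    if (length(object) > 0)
        cat("  read length (mate 1, first pair):",
            nchar(object@seq1[1]), "bp\n")
})

#' K-mer multiplicity spectrum
#'
#' The histogram of canonical k-mer multiplicities: for each multiplicity
#' m, the number of distinct canonical k-mers seen exactly m times.
#'
#' @slot k odd word size.
#' @slot spectrum data.frame with columns `multiplicity` and `count`.
#' @export
setClass("KmerHistogram", representation(
    k = "integer", spectrum = "data.frame"
))

setValidity("KmerHistogram", function(object) {
    if (length(object@k) != 1L || object@k %% 2L == 0L)
        return("k must be a single odd integer")
    sp <- object@spectrum
    if (!all(c("multiplicity", "count") %in% names(sp)))
        return("spectrum needs columns multiplicity, count")
    if (nrow(sp) && any(sp$multiplicity < 1))
        return("multiplicities must be >= 1")
    TRUE
})

#' @describeIn KmerHistogram total k-mer instances (sum of
#'   multiplicity times count)
#' @param x a `KmerHistogram`.
#' @export
kmerInstances <- function(x) {
    stopifnot(is(x, "KmerHistogram"))
    sum(as.numeric(x@spectrum$multiplicity) * x@spectrum$count)
}

setMethod("show", "KmerHistogram", function(object) {
    cat("KmerHistogram (k =", object@k, "):",
        nrow(object@spectrum), "distinct multiplicities,",
        format(kmerInstances(object), big.mark = ","),
        "k-mer instances\n")
})

#' Linked coverage-peak model
#'
#' The fitted pair of linked peaks in a k-mer spectrum: the single-copy
#' peak at multiplicity N and the inverted-repeat peak near 2N, together
#' with the bait multiplicity band and the error/nuclear valley.
#'
#' @slot nSingle single-copy peak multiplicity (N).
#' @slot nIr inverted-repeat peak multiplicity (close to 2N).
#' @slot bandLow,bandHigh inclusive multiplicity bounds for bait k-mers.
#' @slot valley multiplicity separating the error/nuclear signal from the
#'   chloroplast band.
#' @slot ratioTol tolerance on `|nIr/nSingle - 2|`.
#' @export
setClass("PeakModel", representation(
    nSingle = "numeric", nIr = "numeric",
    bandLow = "integer", bandHigh = "integer",
    valley = "numeric", ratioTol = "numeric"
))

setValidity("PeakModel", function(object) {
    if (!(object@bandLow < object@nSingle &&
          object@nSingle < object@nIr &&
          object@nIr < object@bandHigh))
        return("need bandLow < nSingle < nIr < bandHigh")
    if (abs(object@nIr / object@nSingle - 2) > object@ratioTol)
        return("peak ratio outside 2 +/- ratioTol")
    TRUE
})

setMethod("show", "PeakModel", function(object) {
    cat(sprintf(
        "PeakModel: N = %.1f, 2N peak = %.1f, band [%d, %d], valley %.0f\n",
        object@nSingle, object@nIr, object@bandLow, object@bandHigh,
        object@valley))
})

#' Bait k-mer set
#'
#' Canonical k-mers whose multiplicity falls inside the bait band of a
#' [PeakModel].
#'
#' @slot k word size.
#' @slot kmers sorted canonical k-mers.
#' @export
setClass("BaitSet", representation(k = "integer", kmers = "character"))

setValidity("BaitSet", function(object) {
    if (length(object@kmers) && any(nchar(object@kmers) != object@k))
        return("bait k-mers must have length k")
    TRUE
})

setMethod("show", "BaitSet", function(object) {
    cat("BaitSet:", length(object@kmers), "canonical", object@k, "-mers\n")
})

#' Quadripartite region map
#'
#' Labelled spans of the four plastome regions (LSC, IRa, SSC, IRb) on a
#' circular 1-based inclusive coordinate system. A span may wrap the
#' origin (start > end).
#'
#' @slot spans data.frame with columns `region`, `start`, `end`,
#'   `length`.
#' @slot totalLength circle length in bp.
#' @export
setClass("RegionMap", representation(
    spans = "data.frame", totalLength = "integer"
))

setValidity("RegionMap", function(object) {
    sp <- object@spans
    need <- c("LSC", "IRa", "SSC", "IRb")
    if (!setequal(sp$region, need) || nrow(sp) != 4)
        return("spans must contain exactly LSC, IRa, SSC, IRb")
    L <- object@totalLength
    lens <- sp$length
    if (any(lens != circularSpanLength(sp$start, sp$end, L)))
        return("span lengths inconsistent with start/end")
    if (sum(lens) != L)
        return("span lengths must sum to totalLength")
    covered <- logical(L)
    for (i in seq_len(4)) {
        idx <- (seq(0, lens[i] - 1L) + sp$start[i] - 1L) %% L + 1L
        if (any(covered[idx])) return("spans overlap")
        covered[idx] <- TRUE
    }
    if (!all(covered)) return("spans do not cover the circle")
    if (sp$length[sp$region == "IRa"] != sp$length[sp$region == "IRb"])
        return("IRa and IRb lengths differ")
    if (sp$length[sp$region == "LSC"] <= sp$length[sp$region == "SSC"])
        return("LSC must be longer than SSC")
    TRUE
})

setMethod("show", "RegionMap", function(object) {
    cat("RegionMap over", object@totalLength, "bp circle:\n")
    print(object@spans, row.names = FALSE)
})

#' Quadripartite plastome genome
#'
#' A circular chloroplast genome with its region map. Canonical form
#' starts at LSC base 1 in the order LSC, IRa, SSC, IRb; the IR mirror
#' invariant (IRa equals the reverse complement of IRb) is enforced.
#'
#' @slot sequence genome sequence (single character string).
#' @slot regionMap a [RegionMap].
#' @slot provenance one of "simulated", "assembled", "reference".
#' @export
setClass("QuadripartiteGenome", representation(
    sequence = "character", regionMap = "RegionMap",
    provenance = "character"
))

setValidity("QuadripartiteGenome", function(object) {
    if (nchar(object@sequence) != object@regionMap@totalLength)
        return("sequence length != regionMap totalLength")
    if (!object@provenance %in% c("simulated", "assembled", "reference"))
        return("provenance must be simulated/assembled/reference")
    ira <- regionSequence(object, "IRa")
    irb <- regionSequence(object, "IRb")
    if (!identical(ira, revComp(irb)))
        return("IRa is not the exact reverse complement of IRb")
    TRUE
})

setMethod("show", "QuadripartiteGenome", function(object) {
    sp <- object@regionMap@spans
    cat(sprintf(
        "QuadripartiteGenome (%s): %s bp; LSC %d, IRa %d, SSC %d, IRb %d\n",
        object@provenance,
        format(object@regionMap@totalLength, big.mark = ","),
        sp$length[sp$region == "LSC"], sp$length[sp$region == "IRa"],
        sp$length[sp$region == "SSC"], sp$length[sp$region == "IRb"]))
})

#' Simulated quadripartite genome
#'
#' A [QuadripartiteGenome] carrying the simulation seed.
#'
#' @slot seed integer seed used to generate the sequence.
#' @export
setClass("SimulatedGenome", contains = "QuadripartiteGenome",
         representation(seed = "integer"))

#' Genome assembly
#'
#' Scaffolds from the de Bruijn assembler. Gap runs are stored as N
#' stretches inside scaffold sequences.
#'
#' @slot scaffolds scaffold sequences.
#' @slot meta data.frame with per-scaffold `length`, `meanCov`,
#'   `circular`.
#' @slot k word size used.
#' @slot stage provenance tag: initial, refined, rescued or gapfilled.
#' @export
setClass("Assembly", representation(
    scaffolds = "character", meta = "data.frame",
    k = "integer", stage = "character"
))

setValidity("Assembly", function(object) {
    if (!object@stage %in% c("initial", "refined", "rescued", "gapfilled"))
        return("unknown stage tag")
    if (length(object@scaffolds) != nrow(object@meta))
        return("meta rows != number of scaffolds")
    if (length(object@scaffolds)) {
        nonN <- sum(nchar(gsub("N", "", object@scaffolds)))
        if (nonN == 0) return("total non-N length must be > 0")
        if (any(grepl("[^ACGTN]", object@scaffolds)))
            return("scaffolds restricted to ACGTN")
    }
    TRUE
})

setMethod("show", "Assembly", function(object) {
    cat(sprintf(
        "Assembly [%s, k=%d]: %d scaffold(s), total %s bp, N50 %s\n",
        object@stage, object@k, length(object@scaffolds),
        format(sum(nchar(object@scaffolds)), big.mark = ","),
        format(assemblyN50(object), big.mark = ",")))
})

#' Collinear anchor chain
#'
#' Ordered exact unique-match anchors between two genomes, the backbone
#' of a dot-plot style comparison.
#'
#' @slot anchors data.frame with `qstart`, `qend`, `tstart`, `tend`,
#'   `strand`, `length`.
#' @slot qlen,tlen sequence lengths.
#' @export
setClass("AnchorChain", representation(
    anchors = "data.frame", qlen = "integer", tlen = "integer"
))

setValidity("AnchorChain", function(object) {
    a <- object@anchors
    if (nrow(a) > 1) {
        if (any(diff(a$tstart) <= 0))
            return("target spans must be strictly increasing")
        if (any(a$tstart[-1] <= a$tend[-nrow(a)]))
            return("anchors overlap on target")
        q <- a[order(a$qstart), ]
        if (any(q$qstart[-1] <= q$qend[-nrow(q)]))
            return("anchors overlap on query")
    }
    TRUE
})

setMethod("show", "AnchorChain", function(object) {
    cat(sprintf(
        "AnchorChain: %d anchor(s), %s / %s bp covered on query/target\n",
        nrow(object@anchors),
        format(sum(object@anchors$qend - object@anchors$qstart + 1),
               big.mark = ","),
        format(sum(object@anchors$tend - object@anchors$tstart + 1),
               big.mark = ",")))
})

#' Multi-sample variant table
#'
#' Normalized variants merged across samples against one reference, with
#' per-sample presence and triallelic flags.
#'
#' @slot refId reference identifier.
#' @slot refLength reference length in bp.
#' @slot samples sample names.
#' @slot events long-format data.frame: `sample`, `pos`, `ref`, `alt`,
#'   `class` (SNV/INS/DEL).
#' @slot calls per-position summary: `pos`, `class` (SNV/InDel), `ref`,
#'   `alts`, `nAlt`, `triallelic`, `nSamples`.
#' @export
setClass("VariantTable", representation(
    refId = "character", refLength = "integer",
    samples = "character", events = "data.frame", calls = "data.frame"
))

setValidity("VariantTable", function(object) {
    cl <- object@calls
    if (nrow(cl)) {
        if (anyDuplicated(cl[, c("pos", "class")]))
            return("calls must be unique per (pos, class)")
        if (!all(cl$triallelic == (cl$nAlt >= 2)))
            return("triallelic flag must equal (nAlt >= 2)")
    }
    TRUE
})

setMethod("show", "VariantTable", function(object) {
    cat(sprintf(
        "VariantTable vs %s (%s bp): %d positions (%d SNV, %d InDel), %d sample(s), %d triallelic\n",
        object@refId, format(object@refLength, big.mark = ","),
        nrow(object@calls), sum(object@calls$class == "SNV"),
        sum(object@calls$class == "InDel"),
        length(object@samples), sum(object@calls$triallelic)))
})

#' Exon/intron/intergenic partition
#'
#' Disjoint feature categories derived from gene annotation that exactly
#' cover the reference.
#'
#' @slot exon,intron,intergenic [IRanges::IRanges] span sets.
#' @slot refLength reference length.
#' @export
setClass("FeaturePartition", representation(
    exon = "ANY", intron = "ANY", intergenic = "ANY",
    refLength = "integer"
))

setValidity("FeaturePartition", function(object) {
    tot <- sum(IRanges::width(object@exon)) +
        sum(IRanges::width(object@intron)) +
        sum(IRanges::width(object@intergenic))
    if (tot != object@refLength)
        return("feature categories must exactly cover the reference")
    ov <- function(a, b)
        length(IRanges::findOverlaps(a, b)) > 0
    if (ov(object@exon, object@intron) ||
        ov(object@exon, object@intergenic) ||
        ov(object@intron, object@intergenic))
        return("feature categories overlap")
    TRUE
})

setMethod("show", "FeaturePartition", function(object) {
    cat(sprintf(
        "FeaturePartition: exon %s bp, intron %s bp, intergenic %s bp\n",
        format(sum(IRanges::width(object@exon)), big.mark = ","),
        format(sum(IRanges::width(object@intron)), big.mark = ","),
        format(sum(IRanges::width(object@intergenic)), big.mark = ",")))
})

#' Fixed-width window variant track
#'
#' Non-overlapping windows tiled from position 1; the last partial window
#' keeps its true span.
#'
#' @slot window window size in bp.
#' @slot track data.frame with `start`, `end`, `count`.
#' @slot refLength reference length.
#' @export
setClass("WindowTrack", representation(
    window = "integer", track = "data.frame", refLength = "integer"
))

setValidity("WindowTrack", function(object) {
    tr <- object@track
    if (nrow(tr)) {
        if (tr$start[1] != 1L || tr$end[nrow(tr)] != object@refLength)
            return("windows must tile positions 1..refLength")
        if (any(tr$count < 0)) return("negative window count")
    }
    TRUE
})

setMethod("show", "WindowTrack", function(object) {
    cat(sprintf(
        "WindowTrack: %d windows of %d bp, %d variants total\n",
        nrow(object@track), object@window, sum(object@track$count)))
})
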