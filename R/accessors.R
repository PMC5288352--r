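# accessor functions (slot access stays internal)

#' Genome sequence as a character string
#' @param x a [QuadripartiteGenome].
#' @return character scalar.
#' @export
genomeSequence <- function(x) {
    stopifnot(is(x, "QuadripartiteGenome"))
    x@sequence
}

#' Region map of a genome
#' @param x a [QuadripartiteGenome].
#' @return the [RegionMap].
#' @export
regionMap <- function(x) {
    stopifnot(is(x, "QuadripartiteGenome"))
    x@regionMap
}

#' Region spans as a data.frame
#' @param x a [RegionMap] or [QuadripartiteGenome].
#' @return data.frame with columns region, start, end, length.
#' @export
regionSpans <- function(x) {
    if (is(x, "QuadripartiteGenome")) x <- x@regionMap
    stopifnot(is(x, "RegionMap"))
    x@spans
}

#' Extract the sequence of one region
#' @param x a [QuadripartiteGenome].
#' @param region one of "LSC", "IRa", "SSC", "IRb".
#' @return character scalar.
#' @export
regionSequence <- function(x, region) {
    stopifnot(is(x, "QuadripartiteGenome"))
    sp <- x@regionMap@spans
    i <- match(region, sp$region)
    if (is.na(i)) csStop("invalid_region_map", paste("no region", region))
    circularSubstr(x@sequence, sp$start[i], sp$end[i])
}

#' Scaffold sequences of an assembly
#' @param x an [Assembly].
#' @return named character vector.
#' @export
scaffolds <- function(x) {
    stopifnot(is(x, "Assembly"))
    setNames(x@scaffolds, x@meta$id)
}

#' Per-scaffold metadata
#' @param x an [Assembly].
#' @return data.frame with id, length, meanCov, circular.
#' @export
assemblyMeta <- function(x) {
    stopifnot(is(x, "Assembly"))
    x@meta
}

#' Assembly stage tag
#' @param x an [Assembly].
#' @return one of "initial", "refined", "rescued", "gapfilled".
#' @export
assemblyStage <- function(x) {
    stopifnot(is(x, "Assembly"))
    x@stage
}

#' N50 of an assembly
#'
#' Length of the shortest scaffold in the smallest set of longest
#' scaffolds covering half the total assembly length.
#'
#' @param x an [Assembly] or a numeric vector of lengths.
#' @return integer N50 (0 for an empty assembly).
#' @export
assemblyN50 <- function(x) {
    lens <- if (is(x, "Assembly")) nchar(x@scaffolds) else as.numeric(x)
    if (!length(lens)) return(0L)
    lens <- sort(lens, decreasing = TRUE)
    as.integer(lens[which(cumsum(lens) >= sum(lens) / 2)[1]])
}

#' K-mer spectrum as a data.frame
#' @param x a [KmerHistogram].
#' @return data.frame with multiplicity and count.
#' @export
kmerSpectrum <- function(x) {
    stopifnot(is(x, "KmerHistogram"))
    x@spectrum
}

#' Bait k-mers
#' @param x a [BaitSet].
#' @return character vector of canonical k-mers.
#' @export
baitKmers <- function(x) {
    stopifnot(is(x, "BaitSet"))
    x@kmers
}

#' Anchors of a chain as a data.frame
#' @param x an [AnchorChain].
#' @return data.frame qstart, qend, tstart, tend, strand, length.
#' @export
chainAnchors <- function(x) {
    stopifnot(is(x, "AnchorChain"))
    x@anchors
}

#' Fraction of the target covered by chain anchors
#' @param x an [AnchorChain].
#' @return numeric in \[0, 1\].
#' @export
chainCoverage <- function(x) {
    stopifnot(is(x, "AnchorChain"))
    if (!nrow(x@anchors)) return(0)
    sum(x@anchors$tend - x@anchors$tstart + 1) / x@tlen
}

#' Per-position variant summary
#' @param x a [VariantTable].
#' @return data.frame of merged calls.
#' @export
variantCalls <- function(x) {
    stopifnot(is(x, "VariantTable"))
    x@calls
}

#' Per-sample variant events
#' @param x a [VariantTable].
#' @return long-format data.frame of events.
#' @export
variantEvents <- function(x) {
    stopifnot(is(x, "VariantTable"))
    x@events
}

#' Window counts of a track
#' @param x a [WindowTrack].
#' @return data.frame with start, end, count.
#' @export
windowCounts <- function(x) {
    stopifnot(is(x, "WindowTrack"))
    x@track
}
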