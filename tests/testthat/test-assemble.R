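# de Bruijn assembly, k spread, refinement, rescue, gap filling

canonicalSeq <- function(s) pmin(s, revComp(s))

test_that("tiling reads over a repeat-free text give one exact contig", {
    set.seed(101)
    truth <- chlorosmith:::randomDNA(5000, 0.45)
    asm <- assembleOnce(tilingReads(truth), 31L)
    expect_equal(length(scaffolds(asm)), 1L)
    expect_identical(unname(scaffolds(asm)[1]), canonicalSeq(truth))
})

test_that("a circular repeat-free genome assembles to one circular contig", {
    set.seed(102)
    truth <- chlorosmith:::randomDNA(16000, 0.4)
    sim <- simulateReads(truth, chloroCoverage = 40, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         errorRate = 0, seed = 4L)
    asm <- assembleOnce(sim$reads, 31L)
    expect_equal(length(scaffolds(asm)), 1L)
    expect_true(assemblyMeta(asm)$circular[1])
    ctg <- unname(scaffolds(asm)[1])
    expect_equal(nchar(ctg), 16000L)
    doubled <- paste0(truth, truth)
    hit <- grepl(ctg, doubled, fixed = TRUE) ||
        grepl(revComp(ctg), doubled, fixed = TRUE)
    expect_true(hit)
})

test_that("empty input and invalid k are rejected", {
    expect_error(assembleOnce(character(0), 31L),
                 class = "chlorosmith_empty_input")
    expect_error(assembleOnce("ACGTACGTACGT", 4L),
                 class = "chlorosmith_invalid_parameter")
    expect_error(assembleOnce("ACGTACGT", 31L),
                 class = "chlorosmith_invalid_parameter")
    expect_error(assembleSpread("ACGTACGT", c(31L, 41L)),
                 class = "chlorosmith_invalid_parameter")
})

test_that("the k spread picks the word size that resolves a repeat", {
    # 40 bp repeat: collapsed at k=31, unique at k=51
    set.seed(103)
    rpt <- chlorosmith:::randomDNA(40, 0.5)
    truth <- paste0(chlorosmith:::randomDNA(1500, 0.5), rpt,
                    chlorosmith:::randomDNA(1500, 0.5), rpt,
                    chlorosmith:::randomDNA(1500, 0.5))
    reads <- tilingReads(truth)
    a31 <- assembleOnce(reads, 31L)
    a51 <- assembleOnce(reads, 51L)
    expect_gt(length(scaffolds(a31)), 1L)
    expect_equal(length(scaffolds(a51)), 1L)
    best <- assembleSpread(reads, c(31L, 51L),
                           expectedSize = nchar(truth))
    expect_equal(best@k, 51L)
    expect_equal(length(scaffolds(best)), 1L)

    # a single supplied k returns that assembly unchanged
    single <- assembleSpread(reads, 31L)
    expect_identical(scaffolds(single), scaffolds(a31))
})

test_that("assembly is deterministic", {
    fx <- standardSim(1L)
    reads <- fx$sim$reads[1:3000]
    a <- assembleOnce(reads, 41L)
    b <- assembleOnce(reads, 41L)
    expect_identical(scaffolds(a), scaffolds(b))
    expect_identical(assemblyMeta(a), assemblyMeta(b))
})

test_that("refinement is a fixed point on a complete assembly", {
    set.seed(104)
    truth <- chlorosmith:::randomDNA(6000, 0.4)
    sim <- simulateReads(truth, chloroCoverage = 40, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         errorRate = 0, seed = 5L)
    asm <- assembleOnce(sim$reads, 31L)
    ref <- refineIteratively(asm, sim$reads, maxIter = 5L)
    expect_equal(sum(nchar(scaffolds(ref))),
                 sum(nchar(scaffolds(asm))))
    expect_true(attr(ref, "converged"))

    expect_identical(refineIteratively(asm, sim$reads, maxIter = 0L),
                     asm)
})

test_that("refinement recovers a segment the bait band missed", {
    fx <- standardSim(2L)
    reads <- qcFilter(fx$sim$reads)
    lab <- fx$sim$labels
    # drop every baited pair whose fragment touches a 1.5 kb window,
    # emulating a diverged segment invisible to the bait k-mers
    hole <- c(4000L, 5500L)
    inHole <- lab$origin == "chloroplast" &
        lab$start <= hole[2] & (lab$start + lab$fragLen) >= hole[1]
    baitedIds <- setdiff(lab$id[lab$origin == "chloroplast"],
                         lab$id[inHole])
    partial <- reads[match(intersect(baitedIds, reads@id), reads@id)]
    asm0 <- assembleOnce(partial, 31L)
    len0 <- sum(nchar(scaffolds(asm0)))
    ref <- refineIteratively(asm0, reads, maxIter = 5L,
                             expectedSize = 16000L)
    len1 <- sum(nchar(scaffolds(ref)))
    expect_gt(len1, len0 + 1000L)
    expect_lte(length(scaffolds(ref)), length(scaffolds(asm0)))
})

test_that("scaffold-end rescue extends a truncated scaffold", {
    set.seed(105)
    truth <- chlorosmith:::randomDNA(8000, 0.4)
    sim <- simulateReads(truth, chloroCoverage = 50, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         errorRate = 0, seed = 6L)
    # scaffold truncated 300 bp before each truth end
    trunc <- substr(truth, 301, 7700)
    asm <- chlorosmith:::newAssembly(trunc, 50, FALSE, 31L, "initial")
    out <- rescueScaffoldEnds(asm, sim$reads)
    s <- unname(scaffolds(out)[1])
    expect_gt(nchar(s), nchar(trunc) + 400L)
    # fragments are sampled on the circle, so extensions may run
    # through the origin (possibly past both ends): compare against
    # the cyclically repeated truth
    cyc <- strrep(truth, 3)
    expect_true(grepl(s, cyc, fixed = TRUE) ||
                grepl(revComp(s), cyc, fixed = TRUE))

    # an assembly with no reads near its ends is left intact
    far <- chlorosmith:::newAssembly(
        chlorosmith:::randomDNA(2000, 0.5), 50, FALSE, 31L, "initial")
    un <- rescueScaffoldEnds(far, sim$reads[1:50])
    expect_equal(nchar(unname(scaffolds(un)[1])), 2000L)
})

test_that("rescue merges scaffolds that abut in truth", {
    set.seed(106)
    truth <- chlorosmith:::randomDNA(8000, 0.4)
    sim <- simulateReads(truth, chloroCoverage = 50, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         errorRate = 0, seed = 7L)
    a <- substr(truth, 1, 4200)
    b <- substr(truth, 4150, 8000)  # 51 bp overlap
    asm <- chlorosmith:::newAssembly(c(a, b), c(50, 50), c(FALSE, FALSE),
                                     31L, "initial")
    out <- rescueScaffoldEnds(asm, sim$reads)
    expect_equal(length(scaffolds(out)), 1L)
    s <- unname(scaffolds(out)[1])
    expect_true(grepl(truth, s, fixed = TRUE) ||
                grepl(revComp(truth), s, fixed = TRUE))
})

test_that("gap filling restores a sequenced N-gap and keeps dead gaps", {
    set.seed(107)
    truth <- chlorosmith:::randomDNA(8000, 0.4)
    sim <- simulateReads(truth, chloroCoverage = 50, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         errorRate = 0, seed = 8L)
    gapped <- paste0(substr(truth, 1, 3900), strrep("N", 200),
                     substr(truth, 4101, 8000))
    asm <- chlorosmith:::newAssembly(gapped, 50, FALSE, 31L, "initial")
    out <- fillGaps(asm, sim$reads)
    expect_identical(unname(scaffolds(out)[1]), truth)
    expect_equal(attr(out, "gapsRemaining"), 0L)

    # a gap-free scaffold passes through unchanged
    clean <- chlorosmith:::newAssembly(truth, 50, FALSE, 31L, "initial")
    expect_identical(unname(scaffolds(fillGaps(clean, sim$reads))[1]),
                     truth)

    # zero-coverage gap: no reads cover it, the N-run stays
    lab <- sim$labels
    away <- lab$start + lab$fragLen < 3500 | lab$start > 4500
    sparse <- sim$reads[which(away)]
    out2 <- fillGaps(asm, sparse)
    expect_true(grepl("N", unname(scaffolds(out2)[1]), fixed = TRUE))
    expect_equal(attr(out2, "gapsRemaining"), 1L)
})

test_that("each stage never returns a worse-scoring assembly", {
    fx <- standardSim(1L)
    reads <- qcFilter(fx$sim$reads)
    h <- buildHistogram(reads, 31L)
    p <- detectLinkedPeaks(h)
    baited <- baitReads(reads, selectBaitKmers(reads, h, p))
    a0 <- assembleSpread(baited, c(31L, 63L), expectedSize = 16000L)
    a1 <- refineIteratively(a0, reads, maxIter = 2L,
                            expectedSize = 16000L)
    a2 <- rescueScaffoldEnds(a1, reads)
    a3 <- fillGaps(a2, reads)
    worse <- function(a, b)
        chlorosmith:::scoreBetter(b, a, expectedSize = 16000L)
    expect_false(worse(a1, a0))
    expect_false(worse(a2, a1))
    expect_false(worse(a3, a2))
})
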