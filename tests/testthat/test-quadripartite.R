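# IR detection, canonical form, equivalence, anchor chains, slicing

test_that("planted IR coordinates are recovered exactly", {
    g <- scaledGenome(1L)
    map <- findInvertedRepeat(genomeSequence(g), minIrLen = 1000L)
    expect_equal(regionSpans(map), regionSpans(g))
})

test_that("a repeat-free sequence raises NoIRFound", {
    set.seed(201)
    s <- chlorosmith:::randomDNA(8000, 0.5)
    expect_error(suppressWarnings(findInvertedRepeat(s, 1000L)),
                 class = "chlorosmith_no_ir_found")
})

test_that("IR detection survives rotations that cut an IR copy", {
    g <- scaledGenome(2L)
    s <- genomeSequence(g)
    for (start in c(1L, 5000L, 9500L, 14500L)) { # cuts in LSC, IRa, IRb
        rot <- chlorosmith:::rotateSeq(s, start)
        map <- findInvertedRepeat(rot, minIrLen = 1000L)
        sp <- regionSpans(map)
        expect_equal(sp$length[sp$region == "IRa"], 3000L,
                     info = paste("cut at", start))
        expect_equal(sp$length[sp$region == "LSC"], 8000L)
    }
})

test_that("canonicalization is invariant to rotation and strand", {
    g <- scaledGenome(3L)
    s <- genomeSequence(g)
    canon <- canonicalizeGenome(s)
    rot <- canonicalizeGenome(chlorosmith:::rotateSeq(s, 1001L))
    expect_identical(genomeSequence(rot), genomeSequence(canon))
    rc <- canonicalizeGenome(revComp(s))
    expect_identical(genomeSequence(rc), genomeSequence(canon))
    # idempotence
    again <- canonicalizeGenome(canon)
    expect_identical(genomeSequence(again), genomeSequence(canon))
    expect_equal(regionSpans(again), regionSpans(canon))
})

test_that("random rotations of the same genome canonicalize identically", {
    for (sd in 1:5) {
        g <- scaledGenome(sd + 10L)
        s <- genomeSequence(g)
        set.seed(sd)
        starts <- sample.int(nchar(s), 2)
        c1 <- canonicalizeGenome(chlorosmith:::rotateSeq(s, starts[1]))
        c2 <- canonicalizeGenome(chlorosmith:::rotateSeq(s, starts[2]))
        expect_identical(genomeSequence(c1), genomeSequence(c2))
    }
})

test_that("equivalence recognizes rotation, strand and SSC isomers", {
    g <- scaledGenome(4L)
    s <- genomeSequence(g)
    rot <- chlorosmith:::rotateSeq(s, 4321L)
    expect_true(genomesEquivalent(s, rot)$equivalent)
    expect_true(genomesEquivalent(s, revComp(rot))$equivalent)

    flip <- sscFlip(canonicalizeGenome(s))
    eq <- genomesEquivalent(s, flip)
    expect_true(eq$equivalent)
    expect_true(eq$sscFlipped)
    expect_false(genomesEquivalent(s, flip,
                                   allowSscFlip = FALSE)$equivalent)

    # a single substitution breaks equivalence with one mismatch
    mutated <- s
    substr(mutated, 4000, 4000) <- if (substr(s, 4000, 4000) == "A")
        "C" else "A"
    eq2 <- genomesEquivalent(s, mutated)
    expect_false(eq2$equivalent)
    expect_equal(eq2$mismatches, 1L)
})

test_that("equivalence is symmetric", {
    g <- scaledGenome(5L)
    s <- genomeSequence(g)
    flip <- sscFlip(canonicalizeGenome(s))
    expect_true(genomesEquivalent(flip, s)$equivalent)
    expect_true(genomesEquivalent(s, s)$equivalent)
})

test_that("identical sequences give a single full-length anchor", {
    set.seed(202)
    s <- chlorosmith:::randomDNA(5000, 0.4)
    ch <- buildAnchorChain(s, s)
    a <- chainAnchors(ch)
    expect_equal(nrow(a), 1L)
    expect_equal(a$qstart, 1L)
    expect_equal(a$qend, 5000L)
    expect_equal(a$strand, "+")
    expect_equal(chainCoverage(ch), 1)
})

test_that("a planted inversion splits the chain onto the minus strand", {
    set.seed(203)
    target <- chlorosmith:::randomDNA(6000, 0.4)
    query <- paste0(substr(target, 1, 2500),
                    revComp(substr(target, 2501, 3000)),
                    substr(target, 3001, 6000))
    ch <- buildAnchorChain(query, target)
    a <- chainAnchors(ch)
    expect_gte(nrow(a), 3L)
    expect_true(any(a$strand == "-"))
    inv <- a[a$strand == "-", ][1, ]
    expect_gt(inv$tstart, 2400)
    expect_lt(inv$tend, 3100)
})

test_that("unrelated sequences share essentially no anchors", {
    set.seed(204)
    a <- chlorosmith:::randomDNA(5000, 0.5)
    b <- chlorosmith:::randomDNA(5000, 0.5)
    res <- tryCatch(buildAnchorChain(a, b), error = function(e) e)
    if (is(res, "error")) {
        expect_s3_class(res, "chlorosmith_empty_chain")
    } else {
        expect_lt(chainCoverage(res), 0.01)
    }
})

test_that("region slices partition the canonical genome", {
    g <- scaledGenome(6L)
    canon <- canonicalizeGenome(g)
    sl <- sliceRegions(canon)
    expect_equal(nchar(sl$LSC), 8000L)
    expect_equal(nchar(sl$SSC), 2000L)
    expect_equal(nchar(sl$IRa), 3000L)
    expect_equal(nchar(sl$IRb), 3000L)
    expect_equal(nchar(sl$LSC_SSC), nchar(sl$LSC) + nchar(sl$SSC))
    expect_identical(paste0(sl$LSC, sl$IRa, sl$SSC, sl$IRb), sl$whole)
})

test_that("a collapsed-IR assembly is restored to the full circle", {
    g <- scaledGenome(7L)
    sim <- simulateReads(genomeSequence(g), chloroCoverage = 60,
                         nuclearLen = 0L, nuclearCoverage = 0,
                         readLen = 100L, errorRate = 0, seed = 9L)
    asm <- assembleOnce(sim$reads, 31L)
    expect_equal(length(scaffolds(asm)), 3L)
    # the IR scaffold carries roughly twice the single-copy coverage
    covs <- sort(assemblyMeta(asm)$meanCov)
    expect_gt(covs[3] / covs[2], 1.6)
    circle <- restoreQuadripartite(asm)
    expect_equal(nchar(circle), 16000L)
    expect_true(genomesEquivalent(circle, genomeSequence(g))$equivalent)
})

test_that("the IR mirror invariant holds for every simulated genome", {
    for (sd in 1:5) {
        g <- simulateGenome(5000L, 1200L, 1500L, 0.4, seed = sd)
        expect_identical(regionSequence(g, "IRa"),
                         revComp(regionSequence(g, "IRb")))
        sp <- regionSpans(g)
        expect_equal(sum(sp$length), nchar(genomeSequence(g)))
    }
})
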