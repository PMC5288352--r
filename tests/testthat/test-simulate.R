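# simulator: genome architecture, mutation logs, read generation

test_that("simulated genomes have the quadripartite architecture", {
    g <- simulateGenome(83282L, 17776L, 26212L, 0.36, seed = 1L)
    expect_equal(nchar(genomeSequence(g)), 153482L)
    sp <- regionSpans(g)
    expect_equal(sp$length[sp$region == "IRa"], 26212L)
    expect_equal(sp$length[sp$region == "IRb"], 26212L)

    g2 <- simulateGenome(8000L, 2000L, 3000L, 0.5, seed = 7L)
    expect_equal(nchar(genomeSequence(g2)), 16000L)
    expect_identical(regionSequence(g2, "IRa"),
                     revComp(regionSequence(g2, "IRb")))
})

test_that("identical seeds give identical genomes", {
    a <- simulateGenome(8000L, 2000L, 3000L, 0.36, seed = 42L)
    b <- simulateGenome(8000L, 2000L, 3000L, 0.36, seed = 42L)
    expect_identical(genomeSequence(a), genomeSequence(b))
    c <- simulateGenome(8000L, 2000L, 3000L, 0.36, seed = 43L)
    expect_false(identical(genomeSequence(a), genomeSequence(c)))
})

test_that("degenerate genome parameters are rejected", {
    expect_error(simulateGenome(0L, 2000L, 3000L, 0.5, seed = 1L),
                 class = "chlorosmith_invalid_parameter")
    expect_error(simulateGenome(8000L, 2000L, 3000L, 1.2, seed = 1L),
                 class = "chlorosmith_invalid_parameter")
    expect_error(simulateGenome(2000L, 8000L, 3000L, 0.5, seed = 1L),
                 class = "chlorosmith_invalid_parameter")
})

test_that("zero mutation rates give the identity", {
    g <- scaledGenome(3L)
    mut <- mutateGenome(g, snvRate = c(LSC = 0, SSC = 0, IR = 0),
                        indelRate = c(LSC = 0, SSC = 0, IR = 0),
                        seed = 1L)
    expect_identical(mut$sequence, genomeSequence(g))
    expect_equal(nrow(mut$log), 0L)
})

test_that("rates above 0.5 are rejected", {
    g <- scaledGenome(3L)
    expect_error(
        mutateGenome(g, snvRate = c(LSC = 0.6, SSC = 0, IR = 0)),
        class = "chlorosmith_invalid_parameter")
})

test_that("LSC SNV count matches the binomial oracle", {
    # Binomial(n = 80000, p = 0.003): mean 240, sd ~15.5
    g <- simulateGenome(80000L, 10000L, 12000L, 0.4, seed = 5L)
    mut <- mutateGenome(g, snvRate = c(LSC = 0.003, SSC = 0, IR = 0),
                        indelRate = c(LSC = 0, SSC = 0, IR = 0),
                        seed = 6L)
    sp <- regionSpans(g)
    lscEnd <- sp$end[sp$region == "LSC"]
    n <- sum(mut$log$class == "SNV" & mut$log$pos <= lscEnd)
    expect_lt(abs(n - 240), 3 * sqrt(240 * 0.997))
})

test_that("applying the log to the parent reproduces the accession", {
    g <- scaledGenome(4L)
    mut <- mutateGenome(g, seed = 9L)
    expect_gt(nrow(mut$log), 0)
    expect_identical(applyMutationLog(genomeSequence(g), mut$log),
                     mut$sequence)
})

test_that("IR mutations are mirrored and the accession IRs stay exact", {
    g <- scaledGenome(5L)
    mut <- mutateGenome(g, snvRate = c(LSC = 0, SSC = 0, IR = 0.01),
                        indelRate = c(LSC = 0, SSC = 0, IR = 0.002),
                        seed = 7L)
    log <- mut$log
    expect_gt(nrow(log), 0)
    expect_equal(sum(log$mirrored), sum(!log$mirrored))
    # the mutated accession still carries an exact inverted repeat of
    # (at least) the planted length
    map <- findInvertedRepeat(mut$sequence, minIrLen = 1000L)
    sp <- regionSpans(map)
    expect_gte(sp$length[sp$region == "IRa"], 2900L)
})

test_that("InDel lengths respect the configured maximum", {
    g <- scaledGenome(6L)
    mut <- mutateGenome(g, snvRate = c(LSC = 0, SSC = 0, IR = 0),
                        indelRate = c(LSC = 0.005, SSC = 0.005,
                                      IR = 0.002),
                        maxIndelLen = 38L, seed = 8L)
    lens <- abs(nchar(mut$log$alt) - nchar(mut$log$ref))
    expect_true(all(lens >= 1L & lens <= 38L))
    expect_true(all(mut$log$class %in% c("INS", "DEL")))
})

test_that("chloroplast read-pair count follows the coverage arithmetic", {
    gseq <- paste(rep("ACGT", 2500), collapse = "") # 10 kb
    sim <- simulateReads(gseq, chloroCoverage = 50, nuclearLen = 0L,
                         nuclearCoverage = 0, readLen = 100L,
                         seed = 1L)
    expect_equal(length(sim$reads), 2500L)
    expect_equal(nrow(sim$labels), 2500L)
})

test_that("circular sampling yields origin-spanning fragments", {
    g <- scaledGenome(7L)
    sim <- simulateReads(genomeSequence(g), chloroCoverage = 50,
                         nuclearLen = 0L, nuclearCoverage = 0,
                         readLen = 100L, seed = 2L)
    expect_gt(sum(sim$labels$spansOrigin), 0)
    # labels cover every emitted pair exactly once
    expect_identical(sort(sim$labels$id), sort(sim$reads@id))
})

test_that("read simulation is deterministic and validates parameters", {
    g <- scaledGenome(8L)
    a <- simulateReads(genomeSequence(g), chloroCoverage = 10,
                       nuclearLen = 0L, nuclearCoverage = 0,
                       readLen = 100L, seed = 5L)
    b <- simulateReads(genomeSequence(g), chloroCoverage = 10,
                       nuclearLen = 0L, nuclearCoverage = 0,
                       readLen = 100L, seed = 5L)
    expect_identical(a$reads@seq1, b$reads@seq1)
    expect_identical(a$reads@seq2, b$reads@seq2)
    expect_error(
        simulateReads(genomeSequence(g), readLen = 500L,
                      insertMean = 400),
        class = "chlorosmith_invalid_parameter")
    expect_warning(
        simulateReads(genomeSequence(g), chloroCoverage = 1,
                      nuclearLen = 0L, nuclearCoverage = 0,
                      readLen = 150L, insertMean = 250, seed = 1L),
        class = "chlorosmith_short_insert")
})

test_that("FASTQ round trip preserves reads byte for byte", {
    g <- scaledGenome(9L)
    sim <- simulateReads(genomeSequence(g), chloroCoverage = 5,
                         nuclearLen = 0L, nuclearCoverage = 0,
                         readLen = 100L, seed = 3L)
    d <- withr::local_tempdir()
    writePairedFastq(sim$reads, file.path(d, "r1.fastq.gz"),
                     file.path(d, "r2.fastq.gz"))
    back <- readPairedFastq(file.path(d, "r1.fastq.gz"),
                            file.path(d, "r2.fastq.gz"))
    expect_identical(back@seq1, sim$reads@seq1)
    expect_identical(back@seq2, sim$reads@seq2)
    expect_identical(back@qual1, sim$reads@qual1)
    expect_identical(back@id, sim$reads@id)
})
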