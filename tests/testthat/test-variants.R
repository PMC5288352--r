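# variant calling, normalization, merging, densities, windows, VCF IO

test_that("SNV classification follows the transition definition", {
    expect_equal(classifySnv("A", "G"), "transition")
    expect_equal(classifySnv("C", "T"), "transition")
    expect_equal(classifySnv("A", "C"), "transversion")
    expect_equal(classifySnv("G", "T"), "transversion")
    expect_equal(classifySnv(c("A", "T"), c("G", "A")),
                 c("transition", "transversion"))
    expect_error(classifySnv("A", "A"),
                 class = "chlorosmith_invalid_variant")
    expect_error(classifySnv("A", "N"),
                 class = "chlorosmith_invalid_variant")
})

test_that("deletions left-align through repeat context to the anchor", {
    refSeq <- "GGCAAATGG"
    # one A deleted, represented at the rightmost A of the run
    v <- normalizeVariant(list(pos = 5L, ref = "AA", alt = "A"), refSeq)
    expect_equal(v$pos, 3L)
    expect_equal(v$ref, "CA")
    expect_equal(v$alt, "C")
    expect_equal(v$class, "DEL")
    # SNVs are unchanged
    s <- normalizeVariant(list(pos = 4L, ref = "A", alt = "G"), refSeq)
    expect_equal(s[c("pos", "ref", "alt")],
                 list(pos = 4L, ref = "A", alt = "G"))
    expect_error(
        normalizeVariant(list(pos = 4L, ref = "T", alt = "G"), refSeq),
        class = "chlorosmith_ref_mismatch")
})

test_that("normalization is idempotent on random InDels", {
    set.seed(301)
    refSeq <- chlorosmith:::randomDNA(5000, 0.30) # AT-rich, repetitive
    for (i in 1:1000) {
        pos <- sample(100:4900, 1)
        d <- sample(1:10, 1)
        v <- if (runif(1) < 0.5) {
            list(pos = pos,
                 ref = substr(refSeq, pos, pos + d), # deletion
                 alt = substr(refSeq, pos, pos))
        } else {
            list(pos = pos, ref = substr(refSeq, pos, pos),
                 alt = paste0(substr(refSeq, pos, pos),
                              chlorosmith:::randomDNA(d, 0.3)))
        }
        n1 <- normalizeVariant(v, refSeq)
        n2 <- normalizeVariant(n1, refSeq)
        expect_identical(n1, n2)
    }
})

test_that("normalization agrees with bcftools norm", {
    skip_if(Sys.which("bcftools") == "", "bcftools not on PATH")
    set.seed(302)
    refSeq <- chlorosmith:::randomDNA(4000, 0.30)
    vars <- lapply(seq(200, 3800, by = 40), function(pos) {
        d <- sample(1:8, 1)
        if (runif(1) < 0.5)
            list(pos = pos, ref = substr(refSeq, pos, pos + d),
                 alt = substr(refSeq, pos, pos))
        else
            list(pos = pos, ref = substr(refSeq, pos, pos),
                 alt = paste0(substr(refSeq, pos, pos),
                              chlorosmith:::randomDNA(d, 0.3)))
    })
    d <- withr::local_tempdir()
    fa <- file.path(d, "ref.fa")
    writeFasta(c(ref = refSeq), fa)
    vcf <- file.path(d, "in.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        sprintf("##contig=<ID=ref,length=%d>", nchar(refSeq)),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        vapply(vars, function(v) sprintf(
            "ref\t%d\t.\t%s\t%s\t.\tPASS\t.", v$pos, v$ref, v$alt),
            character(1))), vcf)
    out <- system2("bcftools", c("norm", "-f", fa, vcf),
                   stdout = TRUE, stderr = FALSE)
    out <- out[!startsWith(out, "#")]
    fields <- do.call(rbind, strsplit(out, "\t"))
    mine <- t(vapply(vars, function(v) {
        n <- normalizeVariant(v, refSeq)
        c(as.character(n$pos), n$ref, n$alt)
    }, character(3)))
    expect_equal(unname(fields[, 2]), mine[, 1])
    expect_equal(unname(fields[, 4]), mine[, 2])
    expect_equal(unname(fields[, 5]), mine[, 3])
})

test_that("identical genomes yield no variants", {
    g <- scaledGenome(1L)
    calls <- callVariants(genomeSequence(g), genomeSequence(g))
    expect_equal(nrow(calls), 0L)
})

test_that("a single substitution is called at its exact position", {
    g <- scaledGenome(2L)
    refSeq <- genomeSequence(g)
    smp <- refSeq
    old <- substr(smp, 5000, 5000)
    substr(smp, 5000, 5000) <- if (old == "A") "G" else "A"
    calls <- callVariants(smp, refSeq)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$pos, 5000L)
    expect_equal(calls$ref, old)
    expect_equal(calls$class, "SNV")
    if (old == "A") expect_equal(calls$tstv, "transition")
})

test_that("non-collinear inputs are rejected with chain coverage", {
    set.seed(303)
    g <- scaledGenome(3L)
    refSeq <- genomeSequence(g)
    smp <- paste0(substr(refSeq, 1, 6000),
                  chlorosmith:::randomDNA(10000, 0.4))
    err <- tryCatch(callVariants(smp, refSeq), error = function(e) e)
    expect_s3_class(err, "chlorosmith_not_collinear")
    expect_lt(err$coverage, 0.9)
})

test_that("the caller recovers a planted mutation log exactly", {
    g <- scaledGenome(4L)
    refSeq <- genomeSequence(g)
    mut <- mutateGenome(g, seed = 11L)
    calls <- callVariants(mut$sequence, refSeq)
    normLog <- do.call(rbind, lapply(seq_len(nrow(mut$log)),
        function(i) {
            n <- normalizeVariant(mut$log[i, ], refSeq)
            data.frame(pos = n$pos, ref = n$ref, alt = n$alt,
                       stringsAsFactors = FALSE)
        }))
    keyLog <- sort(paste(normLog$pos, normLog$ref, normLog$alt))
    keyCall <- sort(paste(calls$pos, calls$ref, calls$alt))
    expect_identical(keyCall, keyLog)
})

test_that("merging samples pools alleles and flags triallelic sites", {
    s1 <- data.frame(pos = 100L, ref = "A", alt = "G", class = "SNV",
                     stringsAsFactors = FALSE)
    s2 <- data.frame(pos = 100L, ref = "A", alt = "T", class = "SNV",
                     stringsAsFactors = FALSE)
    tab <- mergeSamples(list(x = s1, y = s2), refLength = 1000L)
    cl <- variantCalls(tab)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$nAlt, 2L)
    expect_true(cl$triallelic)
    expect_equal(cl$alts, "G,T")

    tab2 <- mergeSamples(list(x = s1, y = s1), refLength = 1000L)
    expect_false(variantCalls(tab2)$triallelic)
    expect_equal(variantCalls(tab2)$nSamples, 2L)

    attr(s2, "refId") <- "other"
    expect_error(mergeSamples(list(x = s1, y = s2),
                              refId = "reference",
                              refLength = 1000L),
                 class = "chlorosmith_reference_mismatch")
})

test_that("a simulated cohort merges to the pooled truth", {
    g <- scaledGenome(5L)
    refSeq <- genomeSequence(g)
    calls <- list()
    logs <- list()
    for (i in 1:5) {
        mut <- mutateGenome(g, seed = 40L + i,
                            accession = paste0("acc", i))
        calls[[paste0("acc", i)]] <- callVariants(mut$sequence, refSeq)
        logs[[i]] <- mut$log
    }
    tab <- mergeSamples(calls, refLength = nchar(refSeq))
    pooled <- do.call(rbind, logs)
    normPooled <- unique(do.call(rbind, lapply(
        seq_len(nrow(pooled)), function(i) {
            n <- normalizeVariant(pooled[i, ], refSeq)
            data.frame(pos = n$pos,
                       cls = ifelse(n$class == "SNV", "SNV", "InDel"),
                       allele = paste0(n$ref, ">", n$alt),
                       stringsAsFactors = FALSE)
        })))
    truthPositions <- unique(normPooled[, c("pos", "cls")])
    cl <- variantCalls(tab)
    expect_equal(nrow(cl), nrow(truthPositions))
    truthTri <- aggregate(allele ~ pos + cls, normPooled,
                          function(a) length(unique(a)))
    expect_equal(sum(cl$triallelic), sum(truthTri$allele >= 2))
    expect_equal(nrow(variantEvents(tab)),
                 sum(vapply(calls, nrow, integer(1))))
})

test_that("feature partitions follow the annotation arithmetic", {
    ann <- data.frame(type = c("gene", "exon", "exon"),
                      start = c(101L, 101L, 301L),
                      end = c(400L, 200L, 400L),
                      gene = "g1", stringsAsFactors = FALSE)
    fp <- buildFeaturePartition(ann, 1000L)
    expect_equal(sum(IRanges::width(fp@exon)), 200L)
    expect_equal(sum(IRanges::width(fp@intron)), 100L)
    expect_equal(sum(IRanges::width(fp@intergenic)), 700L)

    none <- buildFeaturePartition(
        data.frame(type = character(0), start = integer(0),
                   end = integer(0), gene = character(0)), 500L)
    expect_equal(sum(IRanges::width(none@intergenic)), 500L)

    bad <- data.frame(type = c("gene", "exon"), start = c(101L, 500L),
                      end = c(400L, 600L), gene = "g1",
                      stringsAsFactors = FALSE)
    expect_error(buildFeaturePartition(bad, 1000L),
                 class = "chlorosmith_invalid_annotation")
})

test_that("density rows use count * 1000 / span with report rounding", {
    df <- data.frame(pos = seq_len(100), class = "SNV")
    rep <- densityReport(df, refLength = 10000L)
    expect_equal(rep$density[rep$class == "SNV" & rep$scope == "whole"],
                 10)
    # zero variants give zero density everywhere
    g <- scaledGenome(6L)
    map <- regionMap(canonicalizeGenome(g))
    rep0 <- densityReport(data.frame(pos = integer(0),
                                     class = character(0)),
                          map = map, refLength = 16000L)
    expect_true(all(rep0$density == 0))
    expect_true(all(rep0$display == 0))
})

test_that("region and feature counts are conserved in every report", {
    g <- scaledGenome(7L)
    canon <- canonicalizeGenome(g)
    map <- regionMap(canon)
    set.seed(304)
    df <- data.frame(pos = sample.int(16000L, 400),
                     class = sample(c("SNV", "INS", "DEL"), 400,
                                    replace = TRUE))
    fp <- buildFeaturePartition(
        data.frame(type = c("gene", "exon"), start = c(2001L, 2001L),
                   end = c(6000L, 4000L), gene = "g1"), 16000L)
    rep <- densityReport(df, map = map, features = fp,
                         refLength = 16000L)
    for (cl in c("SNV", "InDel")) {
        sub <- rep[rep$class == cl, ]
        whole <- sub$count[sub$scope == "whole"]
        expect_equal(sum(sub$count[sub$scope %in%
                                   c("LSC", "SSC", "IR")]), whole)
        expect_equal(sum(sub$count[sub$scope %in%
                                   c("exon", "intron", "intergenic")]),
                     whole)
    }
    # density formula round trip
    expect_true(all(abs(rep$density * rep$span / 1000 - rep$count)
                    < 0.5))
})

test_that("window counts bin by position and conserve totals", {
    df <- data.frame(pos = c(100L, 600L, 620L), class = "SNV")
    tr <- windowDensity(df, window = 500L, refLength = 1500L)
    expect_equal(windowCounts(tr)$count, c(1L, 2L, 0L))
    expect_equal(windowCounts(tr)$start, c(1L, 501L, 1001L))
    expect_equal(windowCounts(tr)$end, c(500L, 1000L, 1500L))

    set.seed(305)
    df2 <- data.frame(pos = sample.int(9999L, 300), class = "SNV")
    tr2 <- windowDensity(df2, window = 500L, refLength = 10000L)
    expect_equal(sum(windowCounts(tr2)$count), 300L)
    # trailing partial window keeps its true span
    tr3 <- windowDensity(df, window = 400L, refLength = 1500L)
    expect_equal(tail(windowCounts(tr3)$end, 1), 1500L)
    expect_equal(tail(windowCounts(tr3)$start, 1), 1201L)
})

test_that("hotspot windows recover a planted high-rate segment", {
    set.seed(306)
    bg <- sample.int(20000L, 40)               # sparse background
    hot <- sample(8001:8500, 25, replace = TRUE) # dense 500 bp segment
    df <- data.frame(pos = c(bg, hot), class = "SNV")
    tr <- windowDensity(df, window = 500L, refLength = 20000L)
    hs <- hotspotWindows(tr, 0.95)
    expect_true(any(hs$start == 8001L))
})

test_that("VCF round trip preserves the table", {
    g <- scaledGenome(8L)
    refSeq <- genomeSequence(g)
    calls <- list()
    for (i in 1:3) {
        mut <- mutateGenome(g, seed = 70L + i)
        calls[[paste0("acc", i)]] <- callVariants(mut$sequence, refSeq)
    }
    tab <- mergeSamples(calls, refLength = nchar(refSeq))
    d <- withr::local_tempdir()
    path <- file.path(d, "calls.vcf.gz")
    writeVcfTable(tab, path)
    back <- readVcfTable(path)
    expect_equal(back@refLength, tab@refLength)
    expect_setequal(back@samples, tab@samples)
    key <- function(t) sort(paste(variantEvents(t)$sample,
                                  variantEvents(t)$pos,
                                  variantEvents(t)$ref,
                                  variantEvents(t)$alt))
    expect_identical(key(back), key(tab))
    expect_equal(sum(variantCalls(back)$triallelic),
                 sum(variantCalls(tab)$triallelic))
})

test_that("multi-allelic records merge to one triallelic position", {
    d <- withr::local_tempdir()
    vcf <- file.path(d, "multi.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=ref,length=1000>",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        "ref\t100\t.\tA\tG,T\t.\tPASS\t."), vcf)
    tab <- readVcfTable(vcf)
    cl <- variantCalls(tab)
    expect_equal(nrow(cl), 1L)
    expect_true(cl$triallelic)
})

test_that("symbolic alleles are skipped with a warning, not an error", {
    d <- withr::local_tempdir()
    vcf <- file.path(d, "sym.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=ref,length=1000>",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        "ref\t100\t.\tA\t<DEL>\t.\tPASS\t.",
        "ref\t200\t.\tC\tT\t.\tPASS\t."), vcf)
    expect_warning(tab <- readVcfTable(vcf),
                   class = "chlorosmith_skipped_record")
    expect_equal(variantCalls(tab)$pos, 200L)
})
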