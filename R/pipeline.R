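# orchestration: shared run configuration, staged pipeline, manifest

#' Build a pipeline run configuration
#'
#' All knobs of the five-stage pipeline in one serializable list.
#' Defaults describe the scaled simulation study: an LSC 8,000 /
#' SSC 2,000 / IR 3,000 bp quadripartite genome at 100x chloroplast and
#' 1x nuclear (1 Mb) coverage, 100 bp reads with a 400 bp insert and 1%
#' substitution error.
#'
#' @param seed master seed for the run.
#' @param outDir output directory.
#' @param simulate generate inputs with the simulator (otherwise
#'   `reads1`/`reads2` must point to FASTQ files).
#' @param reads1,reads2 input FASTQ paths when `simulate = FALSE`.
#' @param reference optional reference FASTA for variant calling.
#' @param annotation optional annotation (GFF3 or TSV) for feature
#'   densities.
#' @param lscLen,sscLen,irLen,gcFraction simulated genome dimensions.
#' @param snvRate,indelRate per-region mutation rates of the simulated
#'   accession.
#' @param chloroCoverage,nuclearLen,nuclearCoverage,readLen,insertMean,insertSd,errorRate
#'   read simulation parameters.
#' @param k word size for spectrum and baiting.
#' @param kSpread word sizes for the assembly spread.
#' @param minMeanQ QC mean-quality threshold.
#' @param ratioTol linked-peak ratio tolerance.
#' @param maxIter refinement iteration cap.
#' @param window variant density window size (bp).
#' @param minIrLen minimum IR length for structure resolution.
#' @return a named list of class `csRunConfig`.
#' @export
makeRunConfig <- function(seed = 1L, outDir = tempfile("chlorosmith_"),
                          simulate = TRUE,
                          reads1 = NULL, reads2 = NULL,
                          reference = NULL, annotation = NULL,
                          lscLen = 8000L, sscLen = 2000L,
                          irLen = 3000L, gcFraction = 0.36,
                          snvRate = c(LSC = 0.003, SSC = 0.004,
                                      IR = 5e-04),
                          indelRate = c(LSC = 8e-04, SSC = 8e-04,
                                        IR = 1e-04),
                          chloroCoverage = 100, nuclearLen = 1e6L,
                          nuclearCoverage = 1, readLen = 100L,
                          insertMean = 400, insertSd = 40,
                          errorRate = 0.01,
                          k = 31L, kSpread = c(31L, 41L, 51L, 63L),
                          minMeanQ = 20, ratioTol = 0.15,
                          maxIter = 5L, window = 500L,
                          minIrLen = 1000L) {
    cfg <- as.list(environment())
    class(cfg) <- "csRunConfig"
    cfg
}

#' Write a run configuration as YAML
#' @param config a `csRunConfig`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    prep <- unclass(config)
    # named vectors must serialize as maps, not bare sequences
    for (nm in c("snvRate", "indelRate"))
        prep[[nm]] <- as.list(prep[[nm]])
    yaml::write_yaml(prep, path)
    invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [writeRunConfig()].
#' @return a `csRunConfig` (unknown fields are kept).
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    base <- makeRunConfig()
    for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
    # yaml flattens named vectors to lists
    for (nm in c("snvRate", "indelRate"))
        base[[nm]] <- unlist(base[[nm]])
    for (nm in c("kSpread"))
        base[[nm]] <- as.integer(unlist(base[[nm]]))
    class(base) <- "csRunConfig"
    base
}

#' Run the full pipeline
#'
#' Executes simulate (optional), QC, spectrum + linked-peak detection,
#' baiting, assembly over the k spread, iterative refinement, scaffold
#' end rescue, gap filling, quadripartite resolution and
#' canonicalization, then (when a reference is available) variant
#' calling and density analysis. Every stage's outputs are written
#' under `config$outDir` and recorded with MD5 checksums in a manifest;
#' a stage failure halts the run with the stage name attached.
#'
#' @param config a `csRunConfig` from [makeRunConfig()].
#' @return list with `manifest` (data.frame of stage, file, md5),
#'   `genome` (canonical [QuadripartiteGenome]), `assembly`, `peaks`,
#'   `table` (a [VariantTable] or NULL) and, for simulated runs,
#'   `truth` and `equivalence`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "csRunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list()
    record <- function(stage, file) {
        manifest[[length(manifest) + 1L]] <<- data.frame(
            stage = stage, file = basename(file),
            md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            csStop("stage_failure", sprintf("stage '%s' failed: %s",
                                            name, conditionMessage(e)))
        })
    }
    pth <- function(f) file.path(config$outDir, f)
    writeRunConfig(config, pth("config.yaml"))
    record("config", pth("config.yaml"))

    truth <- NULL; truthLog <- NULL; reference <- NULL; reads <- NULL
    accession <- NULL
    if (isTRUE(config$simulate)) {
        stage("simulate", {
            truth <- simulateGenome(config$lscLen, config$sscLen,
                                     config$irLen, config$gcFraction,
                                     seed = config$seed)
            mut <- mutateGenome(truth, config$snvRate,
                                config$indelRate,
                                seed = config$seed + 1L)
            truthLog <- mut$log
            accession <- mut$sequence
            sim <- simulateReads(mut$sequence,
                                 chloroCoverage = config$chloroCoverage,
                                 nuclearLen = config$nuclearLen,
                                 nuclearCoverage = config$nuclearCoverage,
                                 readLen = config$readLen,
                                 insertMean = config$insertMean,
                                 insertSd = config$insertSd,
                                 errorRate = config$errorRate,
                                 seed = config$seed + 2L)
            writeFasta(c(truth_parent = truth@sequence,
                         truth_accession = mut$sequence),
                       pth("truth.fasta"))
            writeMutationLog(mut$log, pth("mutations.tsv"))
            write.table(sim$labels, pth("read_labels.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            writePairedFastq(sim$reads, pth("reads_1.fastq"),
                             pth("reads_2.fastq"))
            reads <- sim$reads
            reference <- truth@sequence
            record("simulate", pth("truth.fasta"))
            record("simulate", pth("mutations.tsv"))
            record("simulate", pth("reads_1.fastq"))
            record("simulate", pth("reads_2.fastq"))
        })
    } else {
        if (is.null(config$reads1) || is.null(config$reads2) ||
            !file.exists(config$reads1) || !file.exists(config$reads2))
            csStop("missing_input",
                   "reads1/reads2 missing and simulation disabled")
        reads <- readPairedFastq(config$reads1, config$reads2)
        if (!is.null(config$reference))
            reference <- unname(readFasta(config$reference)[1])
    }

    reads <- stage("qc", qcFilter(reads, config$minMeanQ))
    hist <- stage("histogram", buildHistogram(reads, config$k))
    writeHistogram(hist, pth("kmer_histogram.tsv"))
    record("histogram", pth("kmer_histogram.tsv"))
    peaks <- stage("peaks", detectLinkedPeaks(hist, config$ratioTol))
    baits <- stage("baits", selectBaitKmers(reads, hist, peaks))
    writeLines(baitKmers(baits), pth("baits.txt"))
    record("baits", pth("baits.txt"))
    baited <- stage("bait", baitReads(reads, baits))

    expected <- if (isTRUE(config$simulate))
        config$lscLen + config$sscLen + 2L * config$irLen else NULL
    asm <- stage("assemble",
                 assembleSpread(baited, config$kSpread, expected))
    asm <- stage("refine",
                 refineIteratively(asm, reads, config$maxIter,
                                   expectedSize = expected))
    asm <- stage("rescue", rescueScaffoldEnds(asm, reads))
    asm <- stage("gapfill", fillGaps(asm, reads, config$insertMean))
    writeAssemblyFasta(asm, pth("assembly.fasta"))
    writeAssemblyReport(asm, pth("assembly_report.tsv"))
    record("assemble", pth("assembly.fasta"))
    record("assemble", pth("assembly_report.tsv"))

    genome <- stage("partition", {
        circle <- restoreQuadripartite(asm)
        canonicalizeGenome(circle, minIrLen = config$minIrLen,
                           provenance = "assembled")
    })
    writeFasta(c(genome = genome@sequence), pth("genome.fasta"))
    writeRegionMap(genome, pth("regions.tsv"))
    record("partition", pth("genome.fasta"))
    record("partition", pth("regions.tsv"))

    # the reads were simulated from the mutated accession, so that is
    # the sequence the assembly must reproduce
    equivalence <- NULL
    if (!is.null(accession))
        equivalence <- stage("compare",
                             genomesEquivalent(genome, accession))

    table <- NULL
    if (!is.null(reference)) {
        stage("callvars", {
            refCanon <- canonicalizeGenome(
                reference, minIrLen = config$minIrLen,
                provenance = "reference")
            # the assembly's SSC orientation is ambiguous (both isomers
            # are valid unitig walks), and the canonical strand choice
            # of two near-identical genomes can differ when a mutation
            # hits the lexicographic tie-break; call against the most
            # collinear reading
            strandForm <- function(gg) {
                new("QuadripartiteGenome",
                    sequence = paste0(
                        revComp(regionSequence(gg, "LSC")),
                        regionSequence(gg, "IRa"),
                        revComp(regionSequence(gg, "SSC")),
                        regionSequence(gg, "IRb")),
                    regionMap = gg@regionMap,
                    provenance = gg@provenance)
            }
            flip <- canonicalizeGenome(sscFlip(genome))
            cand <- list(genome, flip,
                         strandForm(genome), strandForm(flip))
            covs <- vapply(cand, function(gg) {
                ch <- tryCatch(
                    buildAnchorChain(gg@sequence, refCanon@sequence),
                    error = function(e) NULL)
                if (is.null(ch)) return(0)
                aa <- chainAnchors(ch)
                aa <- aa[aa$strand == "+", , drop = FALSE]
                if (!nrow(aa)) return(0)
                sum(aa$tend - aa$tstart + 1) / nchar(refCanon@sequence)
            }, numeric(1))
            calls <- callVariants(cand[[which.max(covs)]], refCanon,
                                  refId = "reference")
            table <- mergeSamples(list(assembly = calls),
                                   refId = "reference",
                                   refLength = nchar(refCanon@sequence))
            writeVcfTable(table, pth("calls.vcf.gz"))
            record("callvars", pth("calls.vcf.gz"))
            refMap <- findInvertedRepeat(refCanon@sequence,
                                         config$minIrLen)
            features <- if (!is.null(config$annotation))
                buildFeaturePartition(config$annotation,
                                      nchar(refCanon@sequence)) else
                NULL
            dens <- densityReport(table, refMap, features)
            write.table(dens, pth("density.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            record("density", pth("density.tsv"))
            track <- windowDensity(table, config$window)
            writeWindowTrack(track, pth("windows.tsv"))
            record("density", pth("windows.tsv"))
        })
    }

    manifest <- do.call(rbind, manifest)
    write.table(manifest, pth("manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(manifest = manifest, genome = genome, assembly = asm,
         peaks = peaks, table = table, truth = truth,
         accession = accession, truthLog = truthLog,
         equivalence = equivalence)
}
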