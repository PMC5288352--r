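# shared fixtures; kept small so single tests stay fast

# scaled quadripartite genome used throughout (LSC 8000 / SSC 2000 /
# IR 3000)
scaledGenome <- function(seed = 1L) {
    simulateGenome(8000L, 2000L, 3000L, 0.36, seed = seed)
}

# perfect step-1 tiling reads over a linear sequence
tilingReads <- function(seq, readLen = 100L) {
    L <- nchar(seq)
    starts <- seq_len(L - readLen + 1L)
    substring(seq, starts, starts + readLen - 1L)
}

# one cached simulation shared by the k-mer and assembly tests: the
# standard study conditions (100x chloroplast, 1x nuclear of 1 Mb,
# 1% error, 400 bp insert, 100 bp reads)
.simCache <- new.env(parent = emptyenv())
standardSim <- function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(.simCache[[key]])) {
        g <- scaledGenome(seed)
        mut <- mutateGenome(g, seed = seed + 100L)
        sim <- simulateReads(mut$sequence, chloroCoverage = 100,
                             nuclearLen = 1e6L, nuclearCoverage = 1,
                             readLen = 100L, insertMean = 400,
                             insertSd = 40, errorRate = 0.01,
                             seed = seed + 200L)
        .simCache[[key]] <- list(genome = g, mut = mut, sim = sim)
    }
    .simCache[[key]]
}

expectedKmerCoverage <- function(readCov, readLen, k, errorRate) {
    readCov * (readLen - k + 1) / readLen * (1 - errorRate)^k
}

# constant-quality PairedReads from bare sequences
readsFromSeqs <- function(seq1, seq2 = NULL, q = 35L) {
    if (is.null(seq2)) seq2 <- revComp(seq1)
    pairedReads(sprintf("r%04d", seq_along(seq1)), seq1, seq2)
}
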