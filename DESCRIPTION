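Package: chlorosmith
Title: De Novo Chloroplast Genome Assembly by k-mer Baiting and
    Plastome Variant-Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles chloroplast (plastome) genomes de novo from
    whole-genome shotgun paired-end reads using a five-stage pipeline:
    k-mer spectrum construction with detection of the linked single-copy
    and inverted-repeat coverage peaks (N and 2N), bait k-mer selection
    and read extraction, de Bruijn graph assembly over a k spread,
    iterative read re-selection, scaffold-end rescue and gap filling.
    Resolves the circular quadripartite plastome architecture
    (LSC/IRa/SSC/IRb), canonicalizes rotation and orientation, and tests
    genome equivalence via collinear anchor chains. Calls and normalizes
    SNVs and InDels between assemblies and a reference, merges
    multi-sample variant tables, and computes per-region and per-feature
    per-kilobase variant densities and fixed-width window tracks. A
    paired-end read simulator with quadripartite ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
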