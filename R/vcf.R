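# VCF 4.2 import/export of multi-sample variant tables (vcfR container)

#' @importClassesFrom vcfR vcfR
NULL

#' Write a variant table as VCF 4.2
#'
#' One record per variant position; co-located alleles become
#' multi-allelic ALT lists (shorter reference alleles are padded to the
#' longest, VCF-style). Sample presence is encoded as haploid GT allele
#' indices. Contig and source meta lines are written.
#'
#' @param table a [VariantTable].
#' @param path output path; vcfR compresses, so a `.vcf.gz` suffix is
#'   conventional.
#' @return `path`, invisibly.
#' @export
writeVcfTable <- function(table, path) {
    stopifnot(is(table, "VariantTable"))
    ev <- table@events
    samples <- table@samples
    meta <- c("##fileformat=VCFv4.2",
              "##source=chlorosmith",
              sprintf("##contig=<ID=%s,length=%d>", table@refId,
                      table@refLength),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    if (!nrow(ev)) {
        fix <- matrix(character(0), ncol = 8,
                      dimnames = list(NULL, c("CHROM", "POS", "ID",
                                              "REF", "ALT", "QUAL",
                                              "FILTER", "INFO")))
        gt <- matrix(character(0), ncol = 1 + length(samples),
                     dimnames = list(NULL, c("FORMAT", samples)))
        v <- new("vcfR", meta = meta, fix = fix, gt = gt)
        vcfR::write.vcf(v, file = path)
        return(invisible(path))
    }
    rows <- split(seq_len(nrow(ev)), ev$pos)
    fixL <- list(); gtL <- list()
    for (idx in rows[order(as.integer(names(rows)))]) {
        sub <- ev[idx, , drop = FALSE]
        refs <- sub$ref
        longRef <- refs[which.max(nchar(refs))]
        if (!all(substr(longRef, 1L, nchar(refs)) == refs)) {
            # co-located alleles whose refs do not nest: emit per-allele
            for (i in seq_len(nrow(sub))) {
                fixL[[length(fixL) + 1L]] <- c(
                    table@refId, as.character(sub$pos[i]), ".",
                    sub$ref[i], sub$alt[i], ".", "PASS", ".")
                gtRow <- setNames(rep("0", length(samples)), samples)
                gtRow[sub$sample[i]] <- "1"
                gtL[[length(gtL) + 1L]] <- c("GT", gtRow)
            }
            next
        }
        pad <- function(ref, alt)
            paste0(alt, substr(longRef, nchar(ref) + 1L, nchar(longRef)))
        padded <- mapply(pad, sub$ref, sub$alt, USE.NAMES = FALSE)
        alts <- sort(unique(padded))
        gtRow <- setNames(rep("0", length(samples)), samples)
        for (i in seq_len(nrow(sub)))
            gtRow[sub$sample[i]] <- as.character(match(padded[i], alts))
        fixL[[length(fixL) + 1L]] <- c(
            table@refId, as.character(sub$pos[1]), ".", longRef,
            paste(alts, collapse = ","), ".", "PASS", ".")
        gtL[[length(gtL) + 1L]] <- c("GT", gtRow)
    }
    fix <- do.call(rbind, fixL)
    colnames(fix) <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO")
    gt <- do.call(rbind, gtL)
    colnames(gt) <- c("FORMAT", samples)
    v <- new("vcfR", meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(v, file = path)
    invisible(path)
}

#' Read a VCF into a variant table
#'
#' Multi-allelic records are split per alternate allele; shared padding
#' bases are trimmed back to the minimal anchor-base representation.
#' Records with symbolic alleles (e.g. `<DEL>`) are skipped with a
#' warning. Per-sample GT fields define presence; without a GT matrix
#' all variants are attributed to one pseudo-sample.
#'
#' @param path VCF file (plain or gzipped).
#' @param refLength reference length; parsed from the `##contig` meta
#'   line when available.
#' @return a [VariantTable].
#' @export
readVcfTable <- function(path, refLength = NULL) {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) csStop("parse_error", paste0(
                      "malformed VCF '", path, "': ",
                      conditionMessage(e))))
    fix <- v@fix
    gt <- v@gt
    refId <- if (nrow(fix)) fix[1, "CHROM"] else "reference"
    if (is.null(refLength)) {
        contig <- grep("^##contig=", v@meta, value = TRUE)
        m <- regmatches(contig,
                        regexpr("length=[0-9]+", contig))
        refLength <- if (length(m))
            as.integer(sub("length=", "", m[1])) else NA_integer_
    }
    samples <- if (!is.null(gt) && ncol(gt) > 1)
        colnames(gt)[-1] else "sample1"
    events <- list()
    skipped <- 0L
    for (i in seq_len(nrow(fix))) {
        ref <- fix[i, "REF"]
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
        pos <- as.integer(fix[i, "POS"])
        if (is.na(pos) || is.na(ref)) {
            skipped <- skipped + 1L
            next
        }
        symbolic <- grepl("<|>|\\[|\\]", alts)
        if (any(symbolic)) {
            skipped <- skipped + 1L
            alts <- alts[!symbolic]
            if (!length(alts)) next
        }
        carriers <- vector("list", length(alts))
        if (!is.null(gt) && ncol(gt) > 1) {
            for (s in samples) {
                g <- gt[i, s]
                if (is.na(g)) next
                aidx <- suppressWarnings(as.integer(
                    sub("^([0-9.]+).*$", "\\1",
                        strsplit(g, "[:/|]")[[1]][1])))
                if (!is.na(aidx) && aidx >= 1 &&
                    aidx <= length(alts))
                    carriers[[aidx]] <- c(carriers[[aidx]], s)
            }
        } else {
            for (j in seq_along(alts))
                carriers[[j]] <- samples
        }
        for (j in seq_along(alts)) {
            tr <- trimAllelePair(pos, ref, alts[j])
            for (s in carriers[[j]])
                events[[length(events) + 1L]] <- data.frame(
                    sample = s, pos = tr$pos, ref = tr$ref,
                    alt = tr$alt,
                    class = variantClassOf(tr$ref, tr$alt),
                    stringsAsFactors = FALSE)
        }
    }
    if (skipped > 0)
        csWarn("skipped_record",
               sprintf("%d record(s) skipped (symbolic or malformed)",
                       skipped))
    ev <- if (length(events)) do.call(rbind, events) else
        data.frame(sample = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   class = character(0), stringsAsFactors = FALSE)
    if (is.na(refLength)) refLength <- max(c(ev$pos, 1L))
    perSample <- lapply(samples, function(s) {
        sub <- ev[ev$sample == s, c("pos", "ref", "alt", "class")]
        attr(sub, "refId") <- refId
        sub
    })
    names(perSample) <- samples
    mergeSamples(perSample, refId = refId, refLength = refLength)
}
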