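# FASTQ IO for paired reads (Biostrings handles the format and gzip)

#' Construct a PairedReads object
#'
#' @param id read-pair identifiers.
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 mate quality strings (Phred+33); default constant
#'   Q35.
#' @return a [PairedReads] object.
#' @export
pairedReads <- function(id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
    q <- intToUtf8(35L + 33L)
    if (is.null(qual1)) qual1 <- strrep(q, nchar(seq1))
    if (is.null(qual2)) qual2 <- strrep(q, nchar(seq2))
    new("PairedReads", id = as.character(id),
        seq1 = as.character(seq1), seq2 = as.character(seq2),
        qual1 = as.character(qual1), qual2 = as.character(qual2))
}

readFastqFile <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Read paired FASTQ files
#'
#' @param path1,path2 mate FASTQ files (optionally gzipped).
#' @return a [PairedReads] object.
#' @export
readPairedFastq <- function(path1, path2) {
    r1 <- tryCatch(readFastqFile(path1), error = function(e)
        csStop("parse_error", paste0("malformed FASTQ '", path1, "': ",
                                     conditionMessage(e))))
    r2 <- tryCatch(readFastqFile(path2), error = function(e)
        csStop("parse_error", paste0("malformed FASTQ '", path2, "': ",
                                     conditionMessage(e))))
    if (length(r1$id) != length(r2$id))
        csStop("parse_error", "mate files differ in read count")
    new("PairedReads", id = sub("/[12]$", "", r1$id),
        seq1 = r1$seq, seq2 = r2$seq, qual1 = r1$qual, qual2 = r2$qual)
}

#' Write paired FASTQ files
#'
#' @param reads a [PairedReads] object.
#' @param path1,path2 output mate files; a `.gz` suffix triggers gzip.
#' @return `c(path1, path2)`, invisibly.
#' @export
writePairedFastq <- function(reads, path1, path2) {
    writeOne <- function(seqs, quals, ids, path) {
        x <- Biostrings::DNAStringSet(seqs)
        names(x) <- ids
        Biostrings::writeXStringSet(
            x, path, format = "fastq",
            qualities = Biostrings::BStringSet(quals),
            compress = grepl("\\.gz$", path))
    }
    writeOne(reads@seq1, reads@qual1, paste0(reads@id, "/1"), path1)
    writeOne(reads@seq2, reads@qual2, paste0(reads@id, "/2"), path2)
    invisible(c(path1, path2))
}
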