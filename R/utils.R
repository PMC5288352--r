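# low-level helpers shared across modules

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
    cpp_revcomp(as.character(x))
}

# structured conditions: every documented error path gets a condition class
# "chlorosmith_<code>" so callers can dispatch on it
csStop <- function(code, msg, ...) {
    stop(structure(
        class = c(paste0("chlorosmith_", code), "error", "condition"),
        list(message = msg, call = sys.call(-1), ...)
    ))
}

csWarn <- function(code, msg) {
    warning(structure(
        class = c(paste0("chlorosmith_", code), "warning", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

# random DNA with a given GC fraction; caller controls the RNG state
randomDNA <- function(n, gcFraction = 0.5) {
    p <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
           (1 - gcFraction) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

# circular substring, 1-based inclusive; start may exceed end (wraps)
circularSubstr <- function(seq, start, end) {
    L <- nchar(seq)
    start <- ((start - 1) %% L) + 1
    end <- ((end - 1) %% L) + 1
    if (start <= end) {
        substr(seq, start, end)
    } else {
        paste0(substr(seq, start, L), substr(seq, 1, end))
    }
}

# length of a circular span
circularSpanLength <- function(start, end, L) {
    ((end - start) %% L) + 1
}

# rotate a circular sequence so that position `start` becomes position 1
rotateSeq <- function(seq, start) {
    L <- nchar(seq)
    start <- ((start - 1) %% L) + 1
    if (start == 1) return(seq)
    paste0(substr(seq, start, L), substr(seq, 1, start - 1))
}

# Hamming distance between equal-length strings
hammingDist <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    sum(charToRaw(a) != charToRaw(b))
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    if (is.null(names(seqs))) names(x) <- paste0("seq", seq_along(x))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}
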