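# Low-level helpers shared across the pipeline modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Round a value for reporting
#'
#' Rounds half away from zero (the convention used for all reported ages,
#' confidence bounds and frequency summaries), at the reporting boundary only;
#' internal arithmetic stays at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @details A guard of 1e-9 on the scaled value compensates for binary
#'   floating point: means of 2-decimal inputs can land infinitesimally below
#'   an exact half (e.g. `(15.53 + 14.02) / 2`) and must still round up.
#' @export
round_report <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Reverse a character string (used for quality strings, which have no
# complement).
str_rev <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return(s)
    rawToChar(rev(charToRaw(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Pack equal-length strings into a raw matrix (one column per string) for
# vectorised per-position comparisons. nrow = string length.
str_mat <- function(x) {
  n <- unique(nchar(x))
  stopifnot(length(n) == 1L)
  if (n == 0L) return(matrix(raw(0), nrow = 0, ncol = length(x)))
  matrix(charToRaw(paste(x, collapse = "")), nrow = n)
}

# Inverse of str_mat: one string per column.
mat_str <- function(m) {
  vapply(seq_len(ncol(m)), function(j) rawToChar(m[, j]), character(1))
}

#' Convert a Phred+33 quality string to integer scores
#' @param q a single quality string.
#' @return integer vector of Phred scores.
#' @export
qual_to_int <- function(q) as.integer(charToRaw(q)) - 33L

#' Convert integer Phred scores to a Phred+33 quality string
#' @param v integer vector of Phred scores (>= 0).
#' @return a single quality string.
#' @export
int_to_qual <- function(v) {
  if (length(v) == 0L) return("")
  rawToChar(as.raw(as.integer(v) + 33L))
}

#' Construct a read table
#'
#' The pipeline represents reads as a plain `data.frame` with one row per
#' read: `read_id`, `bases` (A/C/G/T/N string) and `quals` (Phred+33 string of
#' the same length). All read-level operations are vectorised over such
#' tables; a single read is just a one-row table.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of base strings.
#' @param quals character vector of Phred+33 quality strings.
#' @return a `data.frame` with columns `read_id`, `bases`, `quals`.
#' @export
read_frame <- function(read_id, bases, quals) {
  stopifnot(length(read_id) == length(bases), length(bases) == length(quals))
  if (any(nchar(bases) != nchar(quals))) {
    stop("bases and quals must have equal per-read lengths")
  }
  if (length(bases) && any(grepl("[^ACGTN]", bases))) {
    stop("bases may contain only A, C, G, T, N")
  }
  data.frame(read_id = as.character(read_id), bases = as.character(bases),
             quals = as.character(quals), stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#' @param reads a read table (see [read_frame()]).
#' @param path output file path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$bases),
    Biostrings::PhredQuality(reads$quals))
  names(x) <- reads$read_id
  # Biostrings warns that the (empty) mcols of the input set are dropped on
  # FASTQ export; nothing of ours is lost.
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = grepl("\\.gz$", path)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Read a FASTQ file into a read table
#' @param path FASTQ file path.
#' @return a read table (see [read_frame()]).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping the (empty) mcols it attaches while
  # parsing FASTQ; nothing of ours is lost.
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  read_frame(names(x), as.character(x),
             as.character(Biostrings::quality(x)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
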