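## Internal sequence utilities. All sequences are handled internally as
## uppercase RNA character strings (A/C/G/U, N allowed where stated); the
## DNA alphabet appears only at I/O edges (oligo output, FASTA input).

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U/N is an
#' error.
#'
#' @param x character vector of nucleotide strings (RNA or DNA).
#' @return character vector in the RNA alphabet.
#' @examples
#' as_rna("acgt")  # "ACGU"
#' @export
as_rna <- function(x) {
  nms <- names(x)
  y <- chartr("T", "U", toupper(as.character(x)))
  names(y) <- nms  # chartr/as.character drop attributes
  bad <- grepl("[^ACGUN]", y)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  y
}

#' Convert an RNA string to DNA (U to T), uppercase
#' @param x character vector in either alphabet.
#' @return DNA character vector.
#' @export
as_dna <- function(x) {
  y <- as_rna(x)
  out <- chartr("U", "T", y)
  names(out) <- names(y)
  out
}

## complement of RNA characters (N stays N)
comp_rna <- function(x) chartr("ACGUN", "UGCAN", x)

#' Reverse complement of a nucleotide string
#'
#' Operates in the internal RNA alphabet; use [as_dna()] on the result if a
#' DNA string is needed.
#'
#' @param x character vector of nucleotide strings.
#' @return reverse complements, RNA alphabet.
#' @export
revcomp <- function(x) {
  vapply(as_rna(x), function(s) {
    paste(rev(strsplit(comp_rna(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a single string into a character vector of bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## 1-based inclusive substring
subseq1 <- function(x, start, end) substr(x, start, end)

#' Read a FASTA/FASTQ file of nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a named
#' character vector normalized to the RNA alphabet. FASTQ qualities are
#' ignored.
#'
#' @param path file path (optionally gzipped).
#' @param format `"fasta"` or `"fastq"`.
#' @return named character vector of sequences (RNA alphabet). Names are the
#'   first whitespace-delimited token of each record header.
#' @export
read_seqs <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  ss <- Biostrings::readBStringSet(path, format = format)
  out <- as_rna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (RNA or DNA alphabet).
#' @param path output path.
#' @param alphabet write as `"dna"` (default, U converted to T) or `"rna"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") as_dna(seqs) else as_rna(seqs)
  ss <- Biostrings::BStringSet(x)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## interval helper: both ends 1-based inclusive
span_width <- function(start, end) end - start + 1L
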