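## Small-RNA processing-accuracy profiling: exact sense-strand read
## mapping onto a hairpin, per-(5' position, length) read stacks, and the
## fraction of reads that are the exactly processed mature species.

#' Map small-RNA reads onto a precursor hairpin
#'
#' Reads are matched as exact sense-strand substrings of the hairpin (no
#' mismatches; qualities ignored). A read matching at k loci is credited
#' 1/k per locus under the default fractional multi-mapping policy. Reads
#' with lengths outside `size_range` are counted in `total_input` but
#' excluded from the matrix and from `total_mapped`.
#'
#' @param reads character vector of read sequences, or a FASTA/FASTQ path.
#' @param p a [precursor()].
#' @param size_range integer length-2, inclusive read-length window
#'   (default 18-26 nt).
#' @param multimap `"fractional"` (1/k per locus) or `"first"` (whole
#'   count at the 5'-most locus).
#' @param format file format when `reads` is a path.
#' @return object of class `read_stack`: `counts` matrix indexed by
#'   (hairpin 5' start position, read length), `total_mapped` (= sum of
#'   the matrix), `total_input`, `precursor_id`.
#' @export
map_reads <- function(reads, p, size_range = c(18L, 26L),
                      multimap = c("fractional", "first"),
                      format = c("fasta", "fastq")) {
  stopifnot(inherits(p, "precursor"))
  multimap <- match.arg(multimap)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGUTNacgutn]+$", reads)) {
    reads <- read_seqs(reads, format = match.arg(format))
  }
  reads <- as_rna(reads)
  lens <- seq.int(size_range[1], size_range[2])
  L <- nchar(p$sequence)
  counts <- matrix(0, nrow = L, ncol = length(lens),
                   dimnames = list(position = seq_len(L), length = lens))
  total_input <- length(reads)
  if (total_input) {
    hp <- Biostrings::BString(p$sequence)
    tab <- table(reads)
    for (rd in names(tab)) {
      w <- nchar(rd)
      if (w < size_range[1] || w > size_range[2]) next
      starts <- Biostrings::start(
        Biostrings::matchPattern(Biostrings::BString(rd), hp))
      if (!length(starts)) next
      n <- as.numeric(tab[[rd]])
      if (multimap == "first") {
        counts[min(starts), as.character(w)] <-
          counts[min(starts), as.character(w)] + n
      } else {
        counts[starts, as.character(w)] <-
          counts[starts, as.character(w)] + n / length(starts)
      }
    }
  }
  structure(list(counts = counts, total_mapped = sum(counts),
                 total_input = total_input, precursor_id = p$id),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("<read_stack> %s: %.1f mapped / %d input reads\n",
              x$precursor_id, x$total_mapped, x$total_input))
  invisible(x)
}

#' Long-format read-stack table
#'
#' @param m a [map_reads()] result.
#' @return data frame `position`, `length`, `count` (non-zero cells only,
#'   plus `rpm` reads-per-million of mapped reads), suitable for
#'   stacked-bar plotting of the read stacks along the hairpin.
#' @export
stack_table <- function(m) {
  stopifnot(inherits(m, "read_stack"))
  idx <- which(m$counts > 0, arr.ind = TRUE)
  out <- data.frame(
    position = as.integer(rownames(m$counts)[idx[, 1]]),
    length = as.integer(colnames(m$counts)[idx[, 2]]),
    count = m$counts[idx])
  out$rpm <- if (m$total_mapped > 0) out$count / m$total_mapped * 1e6 else
    rep(NA_real_, nrow(out))
  out[order(out$position, out$length), , drop = FALSE]
}

#' Summarize precursor processing precision
#'
#' "Accurately processed" means exact 5' and 3' ends: a mapped read is
#' accurate iff its 5' start equals the mature arm's start and its length
#' equals the mature arm's length.
#'
#' @param m a [map_reads()] result built on `p`.
#' @param p the same [precursor()].
#' @return object of class `processing_summary`: `accurate_fraction`,
#'   `other_fraction`, `star_fraction` (the analogous exact-star
#'   fraction), `size_histogram` (mapped counts per read length), and the
#'   totals. All fractions are `NA` when nothing mapped.
#' @export
processing_summary <- function(m, p) {
  stopifnot(inherits(m, "read_stack"), inherits(p, "precursor"))
  if (!identical(m$precursor_id, p$id))
    stop("read stack was built on precursor '", m$precursor_id,
         "', not '", p$id, "'")
  cell <- function(span) {
    w <- span_width(span[1], span[2])
    if (as.character(w) %in% colnames(m$counts))
      m$counts[span[1], as.character(w)] else 0
  }
  tm <- m$total_mapped
  acc <- if (tm > 0) cell(p$mature_span) / tm else NA_real_
  star <- if (tm > 0) cell(p$star_span) / tm else NA_real_
  structure(list(accurate_fraction = acc,
                 other_fraction = if (is.na(acc)) NA_real_ else 1 - acc,
                 star_fraction = star,
                 size_histogram = colSums(m$counts),
                 total_mapped = tm,
                 total_input = m$total_input,
                 precursor_id = p$id),
            class = "processing_summary")
}

#' @export
print.processing_summary <- function(x, ...) {
  cat(sprintf("<processing_summary> %s: accurate %.1f%%, star %.1f%% (%.1f mapped reads)\n",
              x$precursor_id, 100 * x$accurate_fraction,
              100 * x$star_fraction, x$total_mapped))
  invisible(x)
}

#' Compare processing accuracy across precursors
#'
#' @param summaries named list of [processing_summary()] results.
#' @return data frame `name`, `accurate_fraction`, `star_fraction`,
#'   `total_mapped`, sorted by descending accurate fraction with
#'   name-lexicographic tie-breaking.
#' @export
compare_precursors <- function(summaries) {
  if (length(summaries) < 2L)
    stop("compare_precursors needs at least two summaries")
  nms <- names(summaries)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("summaries must carry unique non-empty names")
  tab <- data.frame(
    name = nms,
    accurate_fraction = vapply(summaries, `[[`, numeric(1),
                               "accurate_fraction"),
    star_fraction = vapply(summaries, `[[`, numeric(1), "star_fraction"),
    total_mapped = vapply(summaries, `[[`, numeric(1), "total_mapped"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$accurate_fraction, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
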