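## Foldback (hairpin) model: annotated precursors and distal stem-loop
## anatomy. Coordinates are 1-based inclusive throughout (miRBase
## convention).

#' Construct an annotated MIRNA precursor
#'
#' A precursor is a hairpin sequence with the mature (guide) and star
#' (passenger) arms given as 1-based inclusive coordinate spans. Spans must
#' lie within the sequence, must not overlap, and each arm must be 19-24 nt.
#' `N` is tolerated in the hairpin but not inside either arm (it would
#' poison exact read matching).
#'
#' @param id precursor identifier.
#' @param sequence hairpin sequence 5'->3' (RNA or DNA; stored as RNA).
#' @param mature_span,star_span integer length-2 vectors `c(start, end)`,
#'   1-based inclusive.
#' @return an object of class `precursor` with elements `id`, `sequence`,
#'   `mature_span`, `star_span`.
#' @examples
#' p <- precursor("hp1", paste(rep("ACGU", 25), collapse = ""),
#'                c(1, 21), c(80, 100))
#' @export
precursor <- function(id, sequence, mature_span, star_span) {
  stopifnot(is.character(id), length(id) == 1L)
  sequence <- as_rna(sequence)
  stopifnot(length(sequence) == 1L)
  mature_span <- as.integer(mature_span)
  star_span <- as.integer(star_span)
  L <- nchar(sequence)
  check_span <- function(span, what) {
    if (length(span) != 2L || any(is.na(span)) || span[1] > span[2])
      stop(sprintf("precursor '%s': malformed %s span", id, what))
    if (span[1] < 1L || span[2] > L)
      stop(sprintf("precursor '%s': %s span [%d, %d] outside sequence (length %d)",
                   id, what, span[1], span[2], L))
    w <- span_width(span[1], span[2])
    if (w < 19L || w > 24L)
      stop(sprintf("precursor '%s': %s arm length %d outside [19, 24]",
                   id, what, w))
    if (grepl("N", subseq1(sequence, span[1], span[2]), fixed = TRUE))
      stop(sprintf("precursor '%s': N inside %s arm", id, what))
  }
  check_span(mature_span, "mature")
  check_span(star_span, "star")
  if (mature_span[1] <= star_span[2] && star_span[1] <= mature_span[2])
    stop(sprintf("precursor '%s': mature and star spans overlap", id))
  structure(
    list(id = id, sequence = sequence,
         mature_span = mature_span, star_span = star_span),
    class = "precursor")
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor> %s (%d nt)\n", x$id, nchar(x$sequence)))
  cat(sprintf("  mature: %d..%d (%d nt)  star: %d..%d (%d nt)\n",
              x$mature_span[1], x$mature_span[2],
              span_width(x$mature_span[1], x$mature_span[2]),
              x$star_span[1], x$star_span[2],
              span_width(x$star_span[1], x$star_span[2])))
  invisible(x)
}

#' Mature / star arm sequences of a precursor
#' @param p a [precursor()].
#' @return single RNA string.
#' @export
mature_seq <- function(p) subseq1(p$sequence, p$mature_span[1], p$mature_span[2])

#' @rdname mature_seq
#' @export
star_seq <- function(p) subseq1(p$sequence, p$star_span[1], p$star_span[2])

#' Load annotated precursors from hairpin sequences and a coordinate table
#'
#' @param hairpins named character vector of hairpin sequences (e.g. from
#'   [read_seqs()]), or a path to a FASTA file.
#' @param annotations data frame with columns `hairpin_id`, `mature_start`,
#'   `mature_end`, `star_start`, `star_end` (1-based inclusive), or a path
#'   to a TSV with that header.
#' @return list of [precursor()] objects, one per annotation row, named by
#'   hairpin id.
#' @details Annotation rows naming a hairpin id absent from `hairpins` are a
#'   hard error listing the missing ids; out-of-bounds or overlapping spans
#'   error naming the offending record.
#' @export
load_precursors <- function(hairpins, annotations) {
  if (is.character(hairpins) && is.null(names(hairpins)) &&
      length(hairpins) == 1L && file.exists(hairpins)) {
    hairpins <- read_seqs(hairpins)
  }
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  need <- c("hairpin_id", "mature_start", "mature_end", "star_start", "star_end")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(annotations$hairpin_id, names(hairpins))
  if (length(absent))
    stop("annotation references hairpin id(s) absent from records: ",
         paste(unique(absent), collapse = ", "))
  ps <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    precursor(a$hairpin_id, hairpins[[a$hairpin_id]],
              c(a$mature_start, a$mature_end), c(a$star_start, a$star_end))
  })
  names(ps) <- annotations$hairpin_id
  ps
}

#' Distal stem-loop anatomy of a precursor
#'
#' The distal stem-loop is defined purely from the arm annotations: the
#' residues strictly between the 3' end of the 5'-proximal arm and the 5'
#' end of the 3'-proximal arm. No secondary-structure prediction is
#' involved, so the metric is deterministic and invariant under T/U
#' re-encoding.
#'
#' @param p a [precursor()].
#' @return object of class `foldback_anatomy`: list with `loop_span`
#'   (1-based inclusive; `NULL` when the arms are adjacent), `loop_length`
#'   (nt, >= 0) and `arm_order` (`"mature_first"` or `"star_first"`).
#' @export
distal_loop <- function(p) {
  stopifnot(inherits(p, "precursor"))
  if (p$mature_span[1] < p$star_span[1]) {
    first <- p$mature_span; second <- p$star_span
    arm_order <- "mature_first"
  } else {
    first <- p$star_span; second <- p$mature_span
    arm_order <- "star_first"
  }
  lo <- first[2] + 1L
  hi <- second[1] - 1L
  len <- hi - lo + 1L
  structure(
    list(loop_span = if (len > 0L) c(lo, hi) else NULL,
         loop_length = max(len, 0L),
         arm_order = arm_order),
    class = "foldback_anatomy")
}

#' @export
print.foldback_anatomy <- function(x, ...) {
  cat(sprintf("<foldback_anatomy> loop %d nt (%s)\n",
              x$loop_length, x$arm_order))
  invisible(x)
}

#' Distal stem-loop survey of a precursor cohort
#'
#' @param ps non-empty list of [precursor()] objects.
#' @return list with `table` (data frame `id`, `loop_length`, sorted by id)
#'   and `summary` (`n`, `median`, `q1`, `q3`, `min`, `max`). Quartiles use
#'   [stats::quantile()] type 7; the median is the standard even/odd-n
#'   median.
#' @export
anatomy_survey <- function(ps) {
  if (length(ps) == 0L) stop("anatomy_survey: empty precursor list")
  stopifnot(all(vapply(ps, inherits, logical(1), "precursor")))
  tab <- data.frame(
    id = vapply(ps, `[[`, character(1), "id"),
    loop_length = vapply(ps, function(p) distal_loop(p)$loop_length, integer(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  q <- stats::quantile(tab$loop_length, c(0.25, 0.75), names = FALSE)
  list(table = tab,
       summary = list(n = nrow(tab),
                      median = stats::median(tab$loop_length),
                      q1 = q[1], q3 = q[2],
                      min = min(tab$loop_length),
                      max = max(tab$loop_length)))
}
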