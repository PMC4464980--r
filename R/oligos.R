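## B/c cloning oligonucleotide assembly. An amiRNA insert (amiRNA /
## distal stem-loop / amiRNA*) is synthesized as two overlapping
## oligonucleotides with 4-nt 5' overhangs (forward 5'-CTTG, reverse
## 5'-CATG) for direct ligation into BsaI-cut B/c vectors. Each oligo
## carries the insert region amiRNA + loop + star[1..19]; the star's
## 3'-overhang dinucleotide (CA) is regenerated at the vector junction by
## the palindromic CATG overhang, so both oligos are 44 + loop-length
## bases -- 60 for the 16-nt OsMIR390 distal loop.
##
## The packaged template file carries SYNTHETIC stand-in loop sequences
## (real precursor loops can be substituted via a user template file); the
## layout geometry, overhangs and declared lengths are validated at load.

#' Construct a precursor cloning template
#'
#' @param name template name (e.g. `"OsMIR390"`, `"OsMIR390-AtL"`).
#' @param loop_sequence distal stem-loop sequence (RNA or DNA; may be
#'   empty for degenerate test templates).
#' @param forward_overhang,reverse_overhang 4-nt 5' overhangs (DNA).
#' @param star_overhang expected star positions 20-21 (regenerated by the
#'   reverse overhang at the vector junction).
#' @param duplex_template 21-character string for [build_star()]: `.` =
#'   pair, a letter = literal base.
#' @param oligo_length declared oligo length; must equal
#'   `44 + nchar(loop_sequence)`.
#' @return object of class `precursor_template`.
#' @export
precursor_template <- function(name, loop_sequence,
                               forward_overhang = "CTTG",
                               reverse_overhang = "CATG",
                               star_overhang = "CA",
                               duplex_template = paste(
                                 c("G", rep(".", 18), "C", "A"), collapse = ""),
                               oligo_length = 44L + nchar(loop_sequence)) {
  loop_sequence <- if (nzchar(loop_sequence)) as_rna(loop_sequence) else ""
  if (nchar(forward_overhang) != 4L || nchar(reverse_overhang) != 4L)
    stop("template '", name, "': overhangs must be 4 nt")
  if (nchar(duplex_template) != 21L)
    stop("template '", name, "': duplex template must have 21 positions")
  if (oligo_length != 44L + nchar(loop_sequence))
    stop("template '", name, "': declared oligo length ", oligo_length,
         " inconsistent with loop length ", nchar(loop_sequence),
         " (expected ", 44L + nchar(loop_sequence), "); fixture corrupt")
  structure(list(name = name, loop_sequence = loop_sequence,
                 forward_overhang = toupper(forward_overhang),
                 reverse_overhang = toupper(reverse_overhang),
                 star_overhang = as_rna(star_overhang),
                 duplex_template = duplex_template,
                 oligo_length = as.integer(oligo_length)),
            class = "precursor_template")
}

## expand the compact duplex-template string to build_star() form
template_star_spec <- function(template) {
  ch <- seq_chars(template$duplex_template)
  ifelse(ch == ".", "pair", ch)
}

#' Load the packaged precursor cloning templates
#'
#' Four templates are shipped: `OsMIR390`, `OsMIR390-AtL`, `AtMIR390a-OsL`
#' and `AtMIR390a`. `OsMIR390` and `AtMIR390a-OsL` use the 16-nt OsMIR390
#' distal loop (60-base oligos); the other two use the longer AtMIR390a
#' loop. The packaged loop sequences are synthetic stand-ins with the
#' correct lengths.
#'
#' @param path optional template TSV overriding the packaged file (same
#'   columns as the packaged `precursor_templates_synthetic.tsv`).
#' @return named list of [precursor_template()] objects.
#' @export
load_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "precursor_templates_synthetic.tsv",
                        package = "amirnaforge", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tmpl <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    precursor_template(r$name, r$loop_sequence, r$forward_overhang,
                       r$reverse_overhang, r$star_overhang,
                       r$duplex_template, r$oligo_length)
  })
  names(tmpl) <- tab$name
  if ("OsMIR390" %in% names(tmpl) &&
      nchar(tmpl[["OsMIR390"]]$loop_sequence) != 16L)
    stop("OsMIR390 template loop is not 16 nt; fixture corrupt")
  if ("AtMIR390a-OsL" %in% names(tmpl) &&
      nchar(tmpl[["AtMIR390a-OsL"]]$loop_sequence) != 16L)
    stop("AtMIR390a-OsL template loop is not 16 nt; fixture corrupt")
  tmpl
}

#' Assemble the amiRNA insert duplex for a precursor template
#'
#' Top strand = amiRNA + distal loop + amiRNA*, converted to DNA.
#'
#' @param amirna,star 21-nt sequences (RNA or DNA).
#' @param template a [precursor_template()].
#' @return object of class `amirna_insert`: `top`, `bottom` (reverse
#'   complement of `top`), segment spans `amirna_span`, `loop_span`,
#'   `star_span` (1-based inclusive on the top strand), and `template`
#'   name.
#' @export
assemble_insert <- function(amirna, star, template) {
  stopifnot(inherits(template, "precursor_template"))
  amirna <- as_rna(amirna); star <- as_rna(star)
  if (nchar(amirna) != 21L || nchar(star) != 21L)
    stop("amiRNA and star must each be 21 nt")
  loop <- template$loop_sequence
  top <- as_dna(paste0(amirna, loop, star))
  nl <- nchar(loop)
  structure(list(
    top = top,
    bottom = as_dna(revcomp(top)),
    amirna_span = c(1L, 21L),
    loop_span = if (nl > 0L) c(22L, 21L + nl) else NULL,
    star_span = c(22L + nl, 42L + nl),
    template = template$name), class = "amirna_insert")
}

#' Recover the amiRNA, loop and star from an assembled insert
#'
#' @param insert an [assemble_insert()] result.
#' @return list with `amirna`, `loop`, `star` (RNA alphabet).
#' @export
split_insert <- function(insert) {
  stopifnot(inherits(insert, "amirna_insert"))
  list(amirna = as_rna(subseq1(insert$top, insert$amirna_span[1],
                               insert$amirna_span[2])),
       loop = if (is.null(insert$loop_span)) "" else
         as_rna(subseq1(insert$top, insert$loop_span[1], insert$loop_span[2])),
       star = as_rna(subseq1(insert$top, insert$star_span[1],
                             insert$star_span[2])))
}

#' Emit the forward/reverse cloning oligonucleotides for an insert
#'
#' Forward oligo = forward overhang (5'-CTTG) + top strand through star
#' position 19; reverse oligo = reverse overhang (5'-CATG) + reverse
#' complement of the same region. Annealing yields a perfect duplex with
#' two 4-nt 5' overhangs. For the OsMIR390 template both oligos are 60
#' bases.
#'
#' @param insert an [assemble_insert()] result.
#' @param template the same [precursor_template()] used to assemble it.
#' @return object of class `oligo_pair`: `forward`, `reverse` (DNA,
#'   5'->3'), `insert_top`, `insert_bottom`, `template`.
#' @export
emit_oligos <- function(insert, template) {
  stopifnot(inherits(insert, "amirna_insert"),
            inherits(template, "precursor_template"))
  if (!identical(insert$template, template$name))
    stop("insert was assembled with template '", insert$template,
         "', not '", template$name, "'")
  L <- nchar(insert$top)
  carried <- subseq1(insert$top, 1L, L - 2L)
  star_tail <- as_rna(subseq1(insert$top, L - 1L, L))
  if (!identical(star_tail, template$star_overhang))
    warning("star positions 20-21 (", star_tail, ") differ from the ",
            "template's vector-junction overhang (", template$star_overhang,
            "); the cloned precursor will not reproduce this star 3' end")
  forward <- paste0(template$forward_overhang, carried)
  reverse <- paste0(template$reverse_overhang, as_dna(revcomp(carried)))
  if (nchar(forward) != template$oligo_length ||
      nchar(reverse) != template$oligo_length)
    stop("template '", template$name, "': oligo length ", nchar(forward),
         " differs from declared ", template$oligo_length,
         "; template fixture corrupt")
  structure(list(forward = forward, reverse = reverse,
                 insert_top = insert$top, insert_bottom = insert$bottom,
                 template = template$name), class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> template %s (%d/%d bases)\n", x$template,
              nchar(x$forward), nchar(x$reverse)))
  cat("  F: 5'-", x$forward, "-3'\n", sep = "")
  cat("  R: 5'-", x$reverse, "-3'\n", sep = "")
  invisible(x)
}

#' Check that an oligo pair anneals into a clean 4-nt-overhang duplex
#'
#' @param oligos an [emit_oligos()] result.
#' @return `TRUE` (invisibly) if the duplex region of the reverse oligo is
#'   the exact reverse complement of the forward oligo's; error otherwise.
#' @export
check_annealing <- function(oligos) {
  stopifnot(inherits(oligos, "oligo_pair"))
  f_core <- substr(oligos$forward, 5L, nchar(oligos$forward))
  r_core <- substr(oligos$reverse, 5L, nchar(oligos$reverse))
  if (!identical(r_core, as_dna(revcomp(f_core))))
    stop("oligos do not anneal: duplex regions are not reverse complements")
  invisible(TRUE)
}

#' Screen a sequence for BsaI recognition sites
#'
#' Reports every `GGTCTC` occurrence on the given strand (plus) and every
#' `GAGACC` occurrence (a BsaI site on the opposite strand). Inserts
#' carrying either cannot be cloned into B/c vectors without site
#' disruption.
#'
#' @param x a DNA/RNA string, an `amirna_insert`, or an `oligo_pair` (both
#'   strands of an insert / both oligos are screened via the top/forward
#'   strand plus- and minus-strand patterns).
#' @return data frame `position` (1-based start of the 6-mer), `strand`
#'   (`"+"`/`"-"`); zero rows when clean.
#' @export
screen_bsai <- function(x) {
  if (inherits(x, "amirna_insert")) x <- x$top
  if (inherits(x, "oligo_pair")) {
    tag <- function(df, which) {
      df$oligo <- rep(which, nrow(df))
      df[, c("oligo", "position", "strand"), drop = FALSE]
    }
    out <- rbind(tag(screen_bsai(x$forward), "forward"),
                 tag(screen_bsai(x$reverse), "reverse"))
    rownames(out) <- NULL
    return(out)
  }
  s <- as_dna(x)
  locate <- function(pat) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  plus <- locate("GGTCTC")
  minus <- locate("GAGACC")
  out <- data.frame(position = c(plus, minus),
                    strand = c(rep("+", length(plus)),
                               rep("-", length(minus))),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}
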