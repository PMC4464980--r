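## P-SAMS-style amiRNA design: candidate generation from a target
## transcript, amiRNA* (star) construction under the 2-nt 3'-overhang
## duplex register, and vetting against a background transcriptome.

#' Default amiRNA/amiRNA* duplex template
#'
#' A duplex template lists, for each star position 1..21, either `"pair"`
#' (complement the amiRNA partner under the canonical register in which
#' both strands carry 2-nt 3' overhangs, so star position j pairs amiRNA
#' position 20 - j) or a fixed literal base. The default fixes star
#' position 1 to the AGO-non-preferred `G` (which the forced amiRNA
#' position-19 `C` pairs), pairs positions 2..19, and fixes the unpaired
#' 3'-overhang positions 20..21 to `CA`, the residues the B/c cloning
#' overhang regenerates at the vector junction.
#'
#' @return character vector of length 21.
#' @export
default_star_template <- function() {
  c("G", rep("pair", 18L), "C", "A")
}

#' Build the amiRNA* strand from an amiRNA and a duplex template
#'
#' @param amirna 21-nt amiRNA (RNA or DNA; no N).
#' @param duplex_template per-position template, see
#'   [default_star_template()]. Positions 20 and 21 have no amiRNA partner
#'   under the 2-nt 3'-overhang register and must be literals.
#' @return 21-nt star sequence (RNA alphabet).
#' @export
build_star <- function(amirna, duplex_template = default_star_template()) {
  amirna <- as_rna(amirna)
  if (nchar(amirna) != 21L) stop("amiRNA must be 21 nt")
  if (length(duplex_template) != 21L)
    stop("duplex template must have 21 entries")
  a <- seq_chars(amirna)
  star <- character(21)
  for (j in 1:21) {
    tj <- duplex_template[j]
    if (identical(tj, "pair")) {
      partner <- 20L - j
      if (partner < 1L || partner > 21L)
        stop("star position ", j,
             " has no amiRNA partner under the 2-nt 3'-overhang register; ",
             "use a literal base")
      star[j] <- comp_rna(a[partner])
    } else {
      star[j] <- as_rna(tj)
      if (nchar(star[j]) != 1L) stop("template literal must be one base")
    }
  }
  paste(star, collapse = "")
}

## ungapped alignment of a candidate against its (sense) source window
candidate_alignment <- function(amirna, window) {
  acode <- encode_rna(as_rna(amirna))
  wcode <- encode_rna(as_rna(window))
  states <- c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH")[
    pair_class_matrix[cbind(acode, wcode[22L - (1:21)])]]
  duplex_alignment(states)
}

#' Generate amiRNA design candidates from a target transcript
#'
#' For every 21-nt window of the transcript, the candidate amiRNA is the
#' reverse complement of the window with position 1 forced to `U` (the
#' AGO1-preferred 5' nucleotide) and position 19 forced to `C` (which
#' places the AGO-non-preferred `G` at star position 1 under the 2-nt
#' 3'-overhang register). Windows containing `N` are skipped with a note.
#'
#' @param target_transcript sequence (>= 21 nt) of the intended target.
#' @param scheme [scoring_scheme()] used for the on-target TPS.
#' @param duplex_template star template passed to [build_star()].
#' @return list of `design_candidate` objects, in window order. Each has
#'   `amirna`, `star`, `source_window` (1-based inclusive span on the
#'   target), `substitutions` (data frame `position`, `from`, `to`;
#'   positions only ever 1 and/or 19), `on_target_tps`, and logical `flags`
#'   `five_prime_U`, `c19`, `star_5G`.
#' @export
candidates_from_target <- function(target_transcript,
                                   scheme = scoring_scheme(),
                                   duplex_template = default_star_template()) {
  tseq <- as_rna(target_transcript)
  L <- nchar(tseq)
  if (L < 21L) stop("target transcript shorter than 21 nt")
  out <- list()
  n_skipped <- 0L
  for (s in seq_len(L - 20L)) {
    window <- subseq1(tseq, s, s + 20L)
    if (grepl("N", window, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    raw <- revcomp(window)
    cand <- seq_chars(raw)
    subs <- list()
    if (cand[1] != "U") {
      subs[[length(subs) + 1L]] <- data.frame(position = 1L, from = cand[1],
                                              to = "U")
      cand[1] <- "U"
    }
    if (cand[19] != "C") {
      subs[[length(subs) + 1L]] <- data.frame(position = 19L, from = cand[19],
                                              to = "C")
      cand[19] <- "C"
    }
    amirna <- paste(cand, collapse = "")
    star <- build_star(amirna, duplex_template)
    out[[length(out) + 1L]] <- structure(
      list(amirna = amirna,
           star = star,
           source_window = c(s, s + 20L),
           substitutions = if (length(subs)) do.call(rbind, subs) else
             data.frame(position = integer(), from = character(),
                        to = character()),
           on_target_tps = score_alignment(candidate_alignment(amirna, window),
                                           scheme),
           flags = list(five_prime_U = cand[1] == "U",
                        c19 = cand[19] == "C",
                        star_5G = substr(star, 1, 1) == "G")),
      class = "design_candidate")
  }
  if (n_skipped > 0L)
    message(n_skipped, " window(s) containing N skipped")
  out
}

#' @export
print.design_candidate <- function(x, ...) {
  cat(sprintf("<design_candidate> window %d..%d  on-target TPS %.1f\n",
              x$source_window[1], x$source_window[2], x$on_target_tps))
  cat("  amiRNA : 5'-", x$amirna, "-3'\n", sep = "")
  cat("  amiRNA*: 5'-", x$star, "-3'\n", sep = "")
  invisible(x)
}

#' Vet a design candidate against a transcriptome
#'
#' The on-target TPS is the best (lowest) site score on the intended
#' transcript; off-target hits are all sites with TPS at or below the
#' report cap on every other transcript. A candidate is `optimal` when its
#' on-target TPS is at most `on_target_max` and no off-target interaction
#' scores below `offtarget_floor` -- direct off-target effects then require
#' interactions confined to the weakly complementary `[offtarget_floor,
#' report_cap]` TPS interval.
#'
#' @param candidate a `design_candidate` (or a bare 21-nt amiRNA string).
#' @param intended_transcript_id id of the intended target in
#'   `transcriptome`.
#' @param transcriptome named character vector of transcripts or FASTA
#'   path.
#' @param scheme [scoring_scheme()].
#' @param on_target_max acceptance bound on the on-target TPS (default 1).
#' @param offtarget_floor off-target hits scoring strictly below this
#'   reject the candidate (default 4; the boundary value itself is
#'   allowed).
#' @return object of class `design_report`: list with `candidate`,
#'   `on_target_tps`, `off_target_hits` (a [find_sites()] data frame with
#'   hits on all non-intended transcripts), `optimal`, and
#'   `rejection_reasons`.
#' @export
assess_candidate <- function(candidate, intended_transcript_id, transcriptome,
                             scheme = scoring_scheme(),
                             on_target_max = 1, offtarget_floor = 4) {
  amirna <- if (inherits(candidate, "design_candidate")) candidate$amirna
            else as_rna(candidate)
  if (is.character(transcriptome) && is.null(names(transcriptome)) &&
      length(transcriptome) == 1L && file.exists(transcriptome)) {
    transcriptome <- read_seqs(transcriptome)
  }
  if (!intended_transcript_id %in% names(transcriptome))
    stop("intended transcript '", intended_transcript_id,
         "' absent from transcriptome")
  on_hits <- find_sites(amirna, transcriptome[intended_transcript_id], scheme)
  on_tps <- if (nrow(on_hits)) min(on_hits$tps) else Inf
  others <- transcriptome[setdiff(names(transcriptome),
                                  intended_transcript_id)]
  off_hits <- if (length(others)) find_sites(amirna, others, scheme)
              else find_sites(amirna, stats::setNames(character(0), character(0)),
                              scheme)
  reasons <- character()
  if (on_tps > on_target_max)
    reasons <- c(reasons, sprintf("on-target TPS %.1f exceeds %.1f",
                                  on_tps, on_target_max))
  bad <- off_hits[off_hits$tps < offtarget_floor, , drop = FALSE]
  if (nrow(bad))
    reasons <- c(reasons,
                 sprintf("off-target TPS %.1f < %.1f on %s",
                         bad$tps, offtarget_floor, bad$transcript_id))
  structure(list(candidate = candidate,
                 on_target_tps = on_tps,
                 off_target_hits = off_hits,
                 optimal = length(reasons) == 0L,
                 rejection_reasons = reasons),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> on-target TPS %.1f, %d off-target hit(s), %s\n",
              x$on_target_tps, nrow(x$off_target_hits),
              if (x$optimal) "OPTIMAL" else "rejected"))
  for (r in x$rejection_reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Design optimal amiRNAs against a transcriptome
#'
#' Convenience pipeline: generate candidates from the intended transcript,
#' vet each against the full transcriptome, and rank the optimal ones by
#' (on-target TPS, descending clearance of the worst off-target TPS above
#' the off-target floor, window position).
#'
#' @inheritParams assess_candidate
#' @param max_candidates cap on returned designs.
#' @return data frame: `amirna`, `star`, `window_start`, `on_target_tps`,
#'   `n_offtargets_lt_floor`, `worst_offtarget_tps`, `optimal`, `reasons`.
#' @export
design_amirnas <- function(intended_transcript_id, transcriptome,
                           scheme = scoring_scheme(),
                           on_target_max = 1, offtarget_floor = 4,
                           max_candidates = 10L) {
  if (is.character(transcriptome) && is.null(names(transcriptome)) &&
      length(transcriptome) == 1L && file.exists(transcriptome)) {
    transcriptome <- read_seqs(transcriptome)
  }
  if (!intended_transcript_id %in% names(transcriptome))
    stop("intended transcript '", intended_transcript_id,
         "' absent from transcriptome")
  cands <- candidates_from_target(transcriptome[[intended_transcript_id]],
                                  scheme)
  rows <- lapply(cands, function(cd) {
    rep_ <- assess_candidate(cd, intended_transcript_id, transcriptome,
                             scheme, on_target_max, offtarget_floor)
    data.frame(
      amirna = cd$amirna, star = cd$star,
      window_start = cd$source_window[1],
      on_target_tps = rep_$on_target_tps,
      n_offtargets_lt_floor = sum(rep_$off_target_hits$tps < offtarget_floor),
      worst_offtarget_tps = if (nrow(rep_$off_target_hits))
        min(rep_$off_target_hits$tps) else NA_real_,
      optimal = rep_$optimal,
      reasons = paste(rep_$rejection_reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  clearance <- ifelse(is.na(tab$worst_offtarget_tps), Inf,
                      tab$worst_offtarget_tps - offtarget_floor)
  tab <- tab[order(!tab$optimal, tab$on_target_tps, -clearance,
                   tab$window_start), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, max_candidates)
}
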