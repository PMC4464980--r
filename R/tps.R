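## Allen/TargetFinder-style Target Prediction Score (TPS): additive
## penalties over the 21 amiRNA positions (counted from the amiRNA 5' end),
## doubled inside the 5' core window. Lower TPS = higher complementarity.

PAIR_STATES <- c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH",
                 "TARGET_BULGE", "AMIRNA_BULGE")

#' TPS scoring scheme
#'
#' Penalty constants follow the published TargetFinder scheme: mismatch and
#' single-nucleotide bulge cost 1, a G:U wobble costs 0.5, and every
#' penalty is multiplied by `core_multiplier` when the amiRNA position lies
#' inside `core_window`. Watson-Crick pairs cost 0.
#'
#' @param mismatch_penalty,gu_penalty,bulge_penalty non-negative penalties.
#' @param core_window integer length-2, amiRNA positions (inclusive) of the
#'   5' core in which penalties are doubled.
#' @param core_multiplier multiplier applied inside the core.
#' @param report_cap sites scoring above this TPS are never reported.
#' @param max_gaps maximum number of single-nucleotide bulges (0 or 1).
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mismatch_penalty = 1, gu_penalty = 0.5,
                           bulge_penalty = 1, core_window = c(2L, 13L),
                           core_multiplier = 2, report_cap = 11,
                           max_gaps = 1L) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, bulge_penalty >= 0,
            core_multiplier > 0, max_gaps %in% c(0L, 1L),
            length(core_window) == 2L,
            core_window[1] >= 1L, core_window[2] <= 21L)
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty,
                 bulge_penalty = bulge_penalty,
                 core_window = as.integer(core_window),
                 core_multiplier = core_multiplier,
                 report_cap = report_cap,
                 max_gaps = as.integer(max_gaps)),
            class = "scoring_scheme")
}

## per-position multiplier vector for amiRNA positions 1..21
position_multipliers <- function(scheme) {
  m <- rep(1, 21)
  m[scheme$core_window[1]:scheme$core_window[2]] <- scheme$core_multiplier
  m
}

## integer encoding A=1 C=2 G=3 U=4 N=5
encode_rna <- function(x) {
  codes <- c(A = 1L, C = 2L, G = 3L, U = 4L, N = 5L)
  v <- codes[seq_chars(as_rna(x))]
  unname(v)
}

## 5x5 pair-class lookup: 1 = WC, 2 = GU wobble, 3 = mismatch.
## Indexed [amirna_code, target_code]; any N is a mismatch.
pair_class_matrix <- local({
  m <- matrix(3L, 5, 5)
  m[1, 4] <- 1L  # A:U
  m[4, 1] <- 1L  # U:A
  m[3, 2] <- 1L  # G:C
  m[2, 3] <- 1L  # C:G
  m[3, 4] <- 2L  # G:U wobble
  m[4, 3] <- 2L  # U:G wobble
  m
})

#' Classify a single amiRNA/target base pair
#'
#' @param amirna_nt,target_nt single nucleotides (RNA or DNA alphabet;
#'   vectorized over pairs). `N` in either position is a mismatch.
#' @return `"WATSON_CRICK"`, `"GU_WOBBLE"` or `"MISMATCH"`.
#' @examples
#' pair_class("G", "C")  # WATSON_CRICK
#' pair_class("G", "U")  # GU_WOBBLE
#' @export
pair_class <- function(amirna_nt, target_nt) {
  a <- encode_rna(paste(as_rna(amirna_nt), collapse = ""))
  t <- encode_rna(paste(as_rna(target_nt), collapse = ""))
  if (length(a) != length(t)) stop("pair_class: unequal lengths")
  c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH")[pair_class_matrix[cbind(a, t)]]
}

#' Construct a 21-position amiRNA/target duplex alignment
#'
#' `states` gives, for each amiRNA position 1..21 counted from the amiRNA
#' 5' end, its pairing state. At most one bulge is representable: an
#' `AMIRNA_BULGE` state at the bulged amiRNA position, or (for a bulged
#' target nucleotide, which occupies no amiRNA position) `gap_kind =
#' "target"` with `gap_pos` naming the amiRNA position at which the bulge
#' penalty is charged -- the bulged base sits between amiRNA positions
#' `gap_pos - 1` and `gap_pos`.
#'
#' @param states character vector, length 21, values in
#'   `WATSON_CRICK`, `GU_WOBBLE`, `MISMATCH`, `AMIRNA_BULGE`.
#' @param gap_kind `"none"`, `"amirna"` or `"target"`.
#' @param gap_pos amiRNA position of the bulge (see above); `NA` when
#'   `gap_kind = "none"`.
#' @return object of class `duplex_alignment`.
#' @export
duplex_alignment <- function(states, gap_kind = c("none", "amirna", "target"),
                             gap_pos = NA_integer_) {
  gap_kind <- match.arg(gap_kind)
  stopifnot(length(states) == 21L,
            all(states %in% c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH",
                              "AMIRNA_BULGE")))
  n_ab <- sum(states == "AMIRNA_BULGE")
  if (gap_kind == "amirna") {
    if (n_ab != 1L || states[gap_pos] != "AMIRNA_BULGE")
      stop("gap_kind 'amirna' requires exactly one AMIRNA_BULGE state at gap_pos")
  } else if (n_ab > 0L) {
    stop("AMIRNA_BULGE state requires gap_kind 'amirna'")
  }
  if (gap_kind == "target" && (is.na(gap_pos) || gap_pos < 2L || gap_pos > 21L))
    stop("gap_kind 'target' requires gap_pos in 2..21")
  structure(list(states = states, gap_kind = gap_kind,
                 gap_pos = as.integer(gap_pos),
                 gaps = as.integer(gap_kind != "none")),
            class = "duplex_alignment")
}

#' Score a duplex alignment
#'
#' TPS = sum of per-position penalties (mismatch 1, G:U 0.5, bulge 1 under
#' the default scheme), each multiplied by the core multiplier when the
#' amiRNA position lies in the core window. A bulged target nucleotide is
#' charged at `gap_pos` (see [duplex_alignment()]).
#'
#' @param aln a [duplex_alignment()].
#' @param scheme a [scoring_scheme()].
#' @return numeric TPS (a multiple of 0.5 under the default scheme).
#' @export
score_alignment <- function(aln, scheme = scoring_scheme()) {
  stopifnot(inherits(aln, "duplex_alignment"), inherits(scheme, "scoring_scheme"))
  mult <- position_multipliers(scheme)
  pen <- c(WATSON_CRICK = 0,
           GU_WOBBLE = scheme$gu_penalty,
           MISMATCH = scheme$mismatch_penalty,
           AMIRNA_BULGE = scheme$bulge_penalty)
  s <- sum(pen[aln$states] * mult)
  if (aln$gap_kind == "target")
    s <- s + scheme$bulge_penalty * mult[aln$gap_pos]
  unname(s)
}

## -------------------------------------------------------------------
## site scanning

## gap configurations for a 21-nt amiRNA. Each config maps amiRNA
## positions to offsets from the window 3' end (antiparallel pairing:
## amiRNA position 1 pairs the window's 3'-most base). `off[i]` = NA for a
## bulged amiRNA position.
gap_configs <- function(max_gaps) {
  cfgs <- list(list(kind = "none", pos = NA_integer_, width = 21L,
                    off = 0:20))
  if (max_gaps >= 1L) {
    for (b in 2:20) {  # terminal amiRNA bulges degenerate to shorter windows
      off <- integer(21)
      off[seq_len(b - 1L)] <- 0:(b - 2L)
      off[b] <- NA_integer_
      if (b < 21L) off[(b + 1L):21L] <- (b - 1L):19L
      cfgs[[length(cfgs) + 1L]] <-
        list(kind = "amirna", pos = b, width = 20L, off = off)
    }
    for (k in 1:20) {  # bulged target base between amiRNA positions k, k+1
      off <- c(0:(k - 1L), (k + 1L):21L)
      cfgs[[length(cfgs) + 1L]] <-
        list(kind = "target", pos = k + 1L, width = 22L, off = off)
    }
  }
  cfgs
}

## states of one window under one config (amirna/target int-encoded)
config_states <- function(acode, tcode, start, cfg) {
  states <- character(21)
  end <- start + cfg$width - 1L
  for (i in 1:21) {
    if (is.na(cfg$off[i])) states[i] <- "AMIRNA_BULGE"
    else states[i] <- c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH")[
      pair_class_matrix[acode[i], tcode[end - cfg$off[i]]]]
  }
  states
}

#' Scan transcripts for amiRNA target sites
#'
#' Every transcript window whose alignment to the amiRNA (antiparallel,
#' with up to `max_gaps` single-nucleotide bulges on either strand) scores
#' at or below the report cap yields a hit. For gapped alignments, the
#' best-scoring bulge placement per window start and bulge class is
#' reported. Only the sense strand is scanned (targets are mRNAs).
#'
#' @param amirna 21-nt amiRNA sequence (RNA or DNA; no N).
#' @param transcripts named character vector of transcript sequences, a
#'   single string, or a FASTA path.
#' @param scheme a [scoring_scheme()].
#' @param cap report cap; defaults to `scheme$report_cap`.
#' @param max_gaps override of `scheme$max_gaps`.
#' @return data frame of hits, sorted by ascending TPS then transcript id
#'   then site start: columns `transcript_id`, `start`, `end` (1-based
#'   inclusive site span on the transcript), `tps`, `gap_kind`, `gap_pos`,
#'   `alignment` (one symbol per amiRNA position 5'->3': `:` Watson-Crick,
#'   `o` G:U wobble, `x` mismatch, `-` bulged amiRNA base, with `^` marking
#'   an inserted target base).
#' @export
find_sites <- function(amirna, transcripts, scheme = scoring_scheme(),
                       cap = scheme$report_cap, max_gaps = scheme$max_gaps) {
  amirna <- as_rna(amirna)
  if (nchar(amirna) != 21L) stop("amiRNA must be 21 nt")
  if (grepl("N", amirna, fixed = TRUE)) stop("amiRNA contains N")
  if (is.character(transcripts) && is.null(names(transcripts)) &&
      length(transcripts) == 1L && file.exists(transcripts)) {
    transcripts <- read_seqs(transcripts)
  }
  transcripts <- as_rna(transcripts)
  if (length(transcripts) && is.null(names(transcripts)))
    names(transcripts) <- paste0("transcript_", seq_along(transcripts))
  acode <- encode_rna(amirna)
  mult <- position_multipliers(scheme)
  penal <- c(0, scheme$gu_penalty, scheme$mismatch_penalty)
  cfgs <- gap_configs(max_gaps)
  out <- list()
  for (tid in names(transcripts)) {
    tseq <- transcripts[[tid]]
    L <- nchar(tseq)
    if (L < 21L - max_gaps) next
    tcode <- encode_rna(tseq)
    ## best score per (start, span-width class)
    best <- list()
    for (cfg in cfgs) {
      w <- cfg$width
      n_start <- L - w + 1L
      if (n_start < 1L) next
      starts <- seq_len(n_start)
      sc <- numeric(n_start)
      for (i in 1:21) {
        if (is.na(cfg$off[i])) {
          sc <- sc + scheme$bulge_penalty * mult[i]
        } else {
          tpos <- starts + (w - 1L) - cfg$off[i]
          sc <- sc + penal[pair_class_matrix[cbind(acode[i], tcode[tpos])]] *
            mult[i]
        }
      }
      if (cfg$kind == "target")
        sc <- sc + scheme$bulge_penalty * mult[cfg$pos]
      key <- cfg$kind
      if (is.null(best[[key]])) {
        best[[key]] <- list(score = sc, pos = rep(cfg$pos, n_start))
      } else {
        better <- sc < best[[key]]$score
        best[[key]]$score[better] <- sc[better]
        best[[key]]$pos[better] <- cfg$pos
      }
    }
    for (key in names(best)) {
      w <- c(none = 21L, amirna = 20L, target = 22L)[[key]]
      keep <- which(best[[key]]$score <= cap)
      for (s in keep) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tid, start = s, end = s + w - 1L,
          tps = best[[key]]$score[s],
          gap_kind = key, gap_pos = best[[key]]$pos[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), tps = numeric(),
                      gap_kind = character(), gap_pos = integer(),
                      alignment = character(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits$alignment <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cfg <- matching_config(max_gaps, h$gap_kind, h$gap_pos)
    tcode <- encode_rna(transcripts[[h$transcript_id]])
    alignment_string(config_states(acode, tcode, h$start, cfg),
                     h$gap_kind, h$gap_pos)
  }, character(1))
  hits <- hits[order(hits$tps, hits$transcript_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

matching_config <- function(max_gaps, kind, pos) {
  for (cfg in gap_configs(max_gaps)) {
    if (cfg$kind == kind && (kind == "none" || cfg$pos == pos)) return(cfg)
  }
  stop("no gap configuration for kind ", kind)
}

alignment_string <- function(states, gap_kind = "none", gap_pos = NA) {
  sym <- c(WATSON_CRICK = ":", GU_WOBBLE = "o", MISMATCH = "x",
           AMIRNA_BULGE = "-")
  s <- sym[states]
  if (identical(gap_kind, "target"))
    s <- append(s, "^", after = gap_pos - 1L)
  paste(s, collapse = "")
}

#' Reconstruct the duplex alignment of a reported hit
#'
#' @param amirna the 21-nt amiRNA used in the scan.
#' @param transcript sequence of the hit's transcript.
#' @param hit one row of a [find_sites()] result.
#' @return a [duplex_alignment()].
#' @export
hit_alignment <- function(amirna, transcript, hit) {
  cfg <- matching_config(1L, hit$gap_kind, hit$gap_pos)
  states <- config_states(encode_rna(as_rna(amirna)),
                          encode_rna(as_rna(transcript)), hit$start, cfg)
  duplex_alignment(states, hit$gap_kind,
                   if (hit$gap_kind == "none") NA_integer_ else hit$gap_pos)
}

#' Predicted slicer cleavage position for a target hit
#'
#' Small-RNA-guided cleavage occurs at the phosphodiester bond opposite
#' amiRNA positions 10 and 11. The returned coordinate is the transcript
#' nucleotide paired to amiRNA position 10, i.e. the 5'-terminal nucleotide
#' of the 3' cleavage fragment -- the position at which 5'-RLM-RACE clone
#' ends accumulate. The cleaved bond lies between the returned position and
#' the one before it.
#'
#' @param hit one row of a [find_sites()] result (fields `start`, `end`,
#'   `gap_kind`, `gap_pos`).
#' @return integer transcript coordinate (1-based).
#' @export
predict_cleavage <- function(hit) {
  end <- as.integer(hit$end)
  kind <- as.character(hit$gap_kind)
  pos <- as.integer(hit$gap_pos)
  if (kind == "amirna" && pos %in% c(10L, 11L))
    stop("bulge at amiRNA position ", pos, ": cleavage site ambiguous")
  if (kind == "target" && pos == 11L)
    stop("bulged target base between amiRNA positions 10 and 11: ",
         "cleavage site ambiguous")
  off10 <- switch(kind,
                  none = 9L,
                  amirna = if (pos < 10L) 8L else 9L,
                  target = if (pos <= 10L) 10L else 9L)
  end - off10
}
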