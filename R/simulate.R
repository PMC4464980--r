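## Seed-deterministic synthetic-data generators. Every generator takes an
## explicit seed, restores the caller's RNG state on exit, and emulates
## one of the data classes the analysis modules consume: small-RNA
## libraries with a controlled accurately-processed fraction, target
## transcriptomes with sites planted at exact TPS values, and
## differential-expression tables with a planted under-expressed set.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rna <- function(n_bases) {
  paste(sample(RNA_BASES, n_bases, replace = TRUE), collapse = "")
}

#' Simulate a small-RNA library from a precursor
#'
#' With probability `fidelity` a read is the exact mature species (exact
#' 5' and 3' ends); otherwise a (5' shift, length) pair is drawn
#' uniformly from `shifts` x `lengths` excluding the exact combination,
#' and the corresponding hairpin substring is emitted. Off-register draws
#' that fall outside the hairpin are resampled (tallied in the
#' `resamples` attribute).
#'
#' @param p a [precursor()].
#' @param depth number of reads.
#' @param fidelity probability of the exact mature species, in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical libraries.
#' @param shifts candidate 5'-end shifts for off-register reads.
#' @param lengths candidate lengths for off-register reads.
#' @return character vector of `depth` reads (RNA alphabet), with
#'   attribute `resamples`.
#' @export
simulate_reads <- function(p, depth = 10000L, fidelity = 0.7, seed = 1L,
                           shifts = -3:3, lengths = 18:26) {
  stopifnot(inherits(p, "precursor"), fidelity >= 0, fidelity <= 1)
  mstart <- p$mature_span[1]
  mlen <- span_width(p$mature_span[1], p$mature_span[2])
  L <- nchar(p$sequence)
  combos <- expand.grid(shift = shifts, len = lengths)
  combos <- combos[!(combos$shift == 0L & combos$len == mlen), , drop = FALSE]
  with_seed(seed, {
    accurate <- stats::runif(depth) < fidelity
    reads <- character(depth)
    reads[accurate] <- mature_seq(p)
    resamples <- 0L
    for (i in which(!accurate)) {
      repeat {
        j <- sample.int(nrow(combos), 1L)
        s <- mstart + combos$shift[j]
        e <- s + combos$len[j] - 1L
        if (s >= 1L && e <= L) break
        resamples <- resamples + 1L
      }
      reads[i] <- subseq1(p$sequence, s, e)
    }
    structure(reads, resamples = resamples)
  })
}

## choose target edits realizing an exact TPS value on a perfect-
## complement 21-nt site. Returns the edited site (sense strand, RNA) or
## NULL if unreachable with this amiRNA. Positions are amiRNA positions;
## the site is the transcript window read 5'->3', with amiRNA position i
## opposite site position 22 - i.
plant_site <- function(amirna, tps, core = c(2L, 13L)) {
  if (tps < 0 || tps %% 0.5 != 0)
    stop("planted TPS must be a non-negative multiple of 0.5, got ", tps)
  a <- seq_chars(as_rna(amirna))
  site <- seq_chars(revcomp(paste(a, collapse = "")))
  in_core <- function(i) i >= core[1] & i <= core[2]
  noncore <- setdiff(1:21, core[1]:core[2])
  corepos <- core[1]:core[2]
  pick <- function(x, n = 1L) x[sample.int(length(x), n)]
  gu_ok <- vapply(1:21, function(i) a[i] %in% c("G", "U"), logical(1))
  used <- logical(21)
  apply_edit <- function(i, kind) {
    wob <- if (a[i] == "G") "U" else if (a[i] == "U") "G" else NA
    site[22L - i] <<- if (kind == "gu") wob else {
      avoid <- c(comp_rna(a[i]), wob)
      pick(setdiff(RNA_BASES, avoid[!is.na(avoid)]))
    }
    used[i] <<- TRUE
  }
  remaining <- tps
  if (remaining %% 1 == 0.5) {                # one non-core G:U (0.5)
    cand <- noncore[gu_ok[noncore] & !used[noncore]]
    if (!length(cand)) return(NULL)
    apply_edit(pick(cand), "gu")
    remaining <- remaining - 0.5
  }
  n_nc <- min(remaining, sum(!used[noncore])) # non-core mismatches (1 each)
  if (n_nc > 0) {
    cand <- noncore[!used[noncore]]
    for (i in pick(cand, n_nc)) apply_edit(i, "mm")
    remaining <- remaining - n_nc
  }
  if (remaining %% 2 == 1) {                  # one core G:U (1)
    cand <- corepos[gu_ok[corepos] & !used[corepos]]
    if (!length(cand)) return(NULL)
    apply_edit(pick(cand), "gu")
    remaining <- remaining - 1
  }
  if (remaining > 0) {                        # core mismatches (2 each)
    n_c <- remaining / 2
    cand <- corepos[!used[corepos]]
    if (length(cand) < n_c) return(NULL)
    for (i in pick(cand, n_c)) apply_edit(i, "mm")
  }
  paste(site, collapse = "")
}

#' Simulate a transcriptome with target sites planted at exact TPS values
#'
#' Each planted transcript contains exactly one engineered site whose
#' best [find_sites()] score equals the requested TPS (validated by
#' rescanning; construction is retried if a gapped re-alignment
#' undercuts the request). Background transcripts are rejection-sampled
#' until they contain no site scoring at or below the report cap.
#'
#' @param amirna 21-nt amiRNA.
#' @param planted_tps numeric vector of requested TPS values (multiples
#'   of 0.5).
#' @param background_n number of site-free background transcripts.
#' @param length transcript length (nt).
#' @param seed integer seed.
#' @param scheme [scoring_scheme()].
#' @param max_tries construction attempts per planted transcript.
#' @return named character vector (`planted_1`, ..., `bg_1`, ...) with
#'   attribute `planted` (data frame `id`, `tps`, `site_start`).
#' @export
simulate_transcriptome <- function(amirna, planted_tps = numeric(0),
                                   background_n = 0L, length = 300L,
                                   seed = 1L, scheme = scoring_scheme(),
                                   max_tries = 50L) {
  amirna <- as_rna(amirna)
  stopifnot(nchar(amirna) == 21L, length >= 21L)
  with_seed(seed, {
    seqs <- character(0)
    planted <- list()
    for (k in seq_along(planted_tps)) {
      tps <- planted_tps[k]
      done <- FALSE
      for (try in seq_len(max_tries)) {
        site <- plant_site(amirna, tps, scheme$core_window)
        if (is.null(site))
          stop("TPS ", tps, " unreachable for this amiRNA ",
               "(no G/U at the required positions)")
        pos <- sample.int(length - 20L, 1L)
        tx <- random_rna(length)
        tx <- paste0(subseq1(tx, 1, pos - 1L), site,
                     subseq1(tx, pos + 21L, length))
        hits <- find_sites(amirna, c(x = tx), scheme)
        if (nrow(hits) && min(hits$tps) == tps &&
            sum(hits$tps == tps) >= 1L) {
          id <- paste0("planted_", k)
          seqs[id] <- tx
          planted[[k]] <- data.frame(id = id, tps = tps, site_start = pos)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("could not plant a site at TPS ", tps, " after ", max_tries,
             " attempts")
    }
    for (k in seq_len(background_n)) {
      repeat {
        tx <- random_rna(length)
        if (nrow(find_sites(amirna, c(x = tx), scheme)) == 0L) break
      }
      seqs[paste0("bg_", k)] <- tx
    }
    structure(seqs,
              planted = if (base::length(planted))
                do.call(rbind, planted) else
                  data.frame(id = character(), tps = numeric(),
                             site_start = integer()))
  })
}

#' Simulate a differential-expression table with a planted UNDER set
#'
#' Planted genes receive adjusted p-values below `q_threshold` and
#' negative log2 fold changes; all other genes receive uniform q in
#' `(q_threshold, 1]`, so [classify_de()] recovers the planted set
#' exactly.
#'
#' @param genes character vector of gene ids.
#' @param planted_under subset of `genes` to plant as under-expressed.
#' @param seed integer seed.
#' @param q_threshold classification threshold the plant respects.
#' @return data frame in the DESeq2-results dialect: `gene_id`,
#'   `baseMean`, `log2FoldChange`, `padj`.
#' @export
simulate_de <- function(genes, planted_under = character(0), seed = 1L,
                        q_threshold = 0.01) {
  stopifnot(all(planted_under %in% genes), !anyDuplicated(genes))
  with_seed(seed, {
    n <- length(genes)
    is_planted <- genes %in% planted_under
    q <- numeric(n)
    lfc <- numeric(n)
    q[is_planted] <- stats::runif(sum(is_planted), 0, q_threshold * 0.9)
    lfc[is_planted] <- -stats::runif(sum(is_planted), 0.5, 4)
    q[!is_planted] <- stats::runif(sum(!is_planted), q_threshold, 1)
    lfc[!is_planted] <- stats::rnorm(sum(!is_planted), 0, 1)
    data.frame(gene_id = genes,
               baseMean = stats::rlnorm(n, meanlog = 5, sdlog = 1.5),
               log2FoldChange = lfc,
               padj = q,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full off-target audit input set
#'
#' Generates, for a planted cohort of (TPS, DE status) pairs plus
#' unpredicted background genes, the per-gene TPS hit table and the DE
#' table, with the generating truth attached for bookkeeping checks.
#'
#' @param planted data frame with columns `tps` (multiples of 0.5 in
#'   `[0, 11]`) and `status` (`"UNDER"`, `"OVER"` or `"NS"`), one row per
#'   predicted-target gene.
#' @param n_no_site number of additional genes without predicted sites
#'   (all `NS` unless listed in `no_site_under`).
#' @param no_site_under number of the no-site genes to plant as UNDER.
#' @param seed integer seed.
#' @return list with `de_table` (DESeq2 dialect), `hits` (`gene_id`,
#'   `tps`) and `truth` (per-gene generating status and TPS).
#' @export
simulate_audit <- function(planted, n_no_site = 0L, no_site_under = 0L,
                           seed = 1L) {
  stopifnot(all(c("tps", "status") %in% names(planted)),
            all(planted$status %in% c("UNDER", "OVER", "NS")),
            no_site_under <= n_no_site)
  ids <- sprintf("gene_%03d", seq_len(nrow(planted) + n_no_site))
  pred_ids <- ids[seq_len(nrow(planted))]
  bg_ids <- setdiff(ids, pred_ids)
  truth <- data.frame(
    gene_id = ids,
    tps = c(planted$tps, rep(NA_real_, n_no_site)),
    status = c(planted$status,
               rep(c("UNDER", "NS"),
                   c(no_site_under, n_no_site - no_site_under))),
    stringsAsFactors = FALSE)
  under <- truth$gene_id[truth$status == "UNDER"]
  over <- truth$gene_id[truth$status == "OVER"]
  de <- simulate_de(ids, planted_under = c(under, over), seed = seed)
  ## flip the sign for planted OVER genes
  de$log2FoldChange[de$gene_id %in% over] <-
    abs(de$log2FoldChange[de$gene_id %in% over])
  list(de_table = de,
       hits = data.frame(gene_id = pred_ids, tps = planted$tps,
                         stringsAsFactors = FALSE),
       truth = truth)
}
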