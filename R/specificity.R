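## Off-target specificity audit: differential-expression status
## classification, TPS binning of predicted targets, enrichment testing,
## and 5'-RLM-RACE clone tallies against the canonical cleavage site.

#' Classify differential-expression status from a DE results table
#'
#' Consumes a gene-level differential-expression table (e.g. DESeq2
#' results): status is `UNDER` when `qvalue < q_threshold` and `log2fc <
#' 0`, `OVER` when `qvalue < q_threshold` and `log2fc > 0`, otherwise
#' `NS`. Genes with a missing q-value are `NS`.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `qvalue`
#'   (and optionally `base_mean`); the DESeq2-results dialect
#'   (`baseMean`, `log2FoldChange`, `padj`) is accepted. May be a TSV
#'   path.
#' @param q_threshold adjusted-p threshold (default 0.01, a 1% FDR).
#' @param counts optional matrix/data frame of per-sample raw counts
#'   (rows matching `table$gene_id`): genes with zero counts in at least
#'   `min_zero_samples` samples are removed before classification.
#' @param min_zero_samples zero-count filter threshold (default 5, of the
#'   8 samples in a 4-vs-4 comparison).
#' @return data frame `gene_id`, `base_mean`, `log2fc`, `qvalue`,
#'   `status` (factor UNDER/OVER/NS).
#' @export
classify_de <- function(table, q_threshold = 0.01, counts = NULL,
                        min_zero_samples = 5L) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  nm <- names(table)
  ali <- c(log2FoldChange = "log2fc", padj = "qvalue", baseMean = "base_mean")
  for (a in names(ali)) if (a %in% nm && !(ali[[a]] %in% nm))
    names(table)[names(table) == a] <- ali[[a]]
  if (!all(c("gene_id", "log2fc", "qvalue") %in% names(table)))
    stop("DE table needs columns gene_id, log2fc, qvalue ",
         "(or the DESeq2 names log2FoldChange, padj)")
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene_id in DE table: ",
         paste(unique(table$gene_id[duplicated(table$gene_id)]), collapse = ", "))
  if (!"base_mean" %in% names(table)) table$base_mean <- NA_real_
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || !all(table$gene_id %in% rownames(counts)))
      stop("counts must carry rownames covering every gene_id")
    nz <- rowSums(counts[table$gene_id, , drop = FALSE] == 0)
    table <- table[nz < min_zero_samples, , drop = FALSE]
  }
  status <- rep("NS", nrow(table))
  sig <- !is.na(table$qvalue) & table$qvalue < q_threshold
  status[sig & table$log2fc < 0] <- "UNDER"
  status[sig & table$log2fc > 0] <- "OVER"
  out <- data.frame(gene_id = table$gene_id, base_mean = table$base_mean,
                    log2fc = table$log2fc, qvalue = table$qvalue,
                    status = factor(status, levels = c("UNDER", "OVER", "NS")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin genes by their best Target Prediction Score
#'
#' Each predicted-target gene is assigned to the bin of its minimum TPS
#' across sites (ties toward the 5'-most site are immaterial for
#' binning); genes without any predicted site form the `no_site` stratum.
#' Bins are 0.5 wide, matching the TPS granularity; integer bins can be
#' derived by aggregation.
#'
#' @param records a [classify_de()] result.
#' @param hits data frame with columns `gene_id` and `tps` (e.g. a
#'   [find_sites()] result with `transcript_id` mapped to genes; that
#'   column name is accepted). Multiple rows per gene are reduced to the
#'   minimum.
#' @param interval closed TPS interval summarized separately (default
#'   `c(4, 11)`, the band in which direct off-target effects of an
#'   optimally designed amiRNA can occur).
#' @return object of class `tps_bin_report`: `bins` (data frame `bin`,
#'   `n_total`, `n_under`, `n_over`, `n_ns` over bins 0, 0.5, ..., 11),
#'   `no_site` (same counts for unpredicted genes), and `interval`
#'   (closed-bound totals plus `prop_under`).
#' @export
bin_by_tps <- function(records, hits, interval = c(4, 11)) {
  stopifnot(all(c("gene_id", "status") %in% names(records)))
  if (!"gene_id" %in% names(hits) && "transcript_id" %in% names(hits))
    names(hits)[names(hits) == "transcript_id"] <- "gene_id"
  stopifnot(all(c("gene_id", "tps") %in% names(hits)))
  unknown <- setdiff(unique(hits$gene_id), records$gene_id)
  if (length(unknown)) {
    warning("hits for gene(s) absent from DE records skipped: ",
            paste(unknown, collapse = ", "))
    hits <- hits[!hits$gene_id %in% unknown, , drop = FALSE]
  }
  min_tps <- if (nrow(hits))
    tapply(hits$tps, hits$gene_id, min) else numeric(0)
  gene_tps <- min_tps[match(records$gene_id, names(min_tps))]
  bins <- seq(0, 11, by = 0.5)
  count_block <- function(sel) {
    st <- records$status[sel]
    c(n_total = sum(sel), n_under = sum(st == "UNDER"),
      n_over = sum(st == "OVER"), n_ns = sum(st == "NS"))
  }
  bin_tab <- do.call(rbind, lapply(bins, function(b)
    count_block(!is.na(gene_tps) & gene_tps == b)))
  bin_tab <- data.frame(bin = bins, bin_tab)
  no_site <- count_block(is.na(gene_tps))
  in_int <- !is.na(gene_tps) & gene_tps >= interval[1] & gene_tps <= interval[2]
  int_counts <- count_block(in_int)
  structure(list(
    bins = bin_tab,
    no_site = as.list(no_site),
    interval = c(list(lower = interval[1], upper = interval[2]),
                 as.list(int_counts),
                 list(prop_under = if (int_counts[["n_total"]] > 0)
                   int_counts[["n_under"]] / int_counts[["n_total"]] else
                     NA_real_))),
    class = "tps_bin_report")
}

#' @export
print.tps_bin_report <- function(x, ...) {
  cat(sprintf("<tps_bin_report> %d predicted genes in [%g, %g] (%.2f%% under), %d without site\n",
              x$interval$n_total, x$interval$lower, x$interval$upper,
              100 * x$interval$prop_under, x$no_site$n_total))
  invisible(x)
}

#' Test predicted off-targets for preferential under-expression
#'
#' Two-sided Fisher exact test on the 2x2 table {gene predicted in the
#' TPS interval vs gene without predicted site} x {differentially
#' under-expressed vs not}. The two-sided p sums all tables with
#' hypergeometric probability at most that of the observed table (the
#' standard definition; no mid-p correction).
#'
#' @param report a [bin_by_tps()] result, or a 2x2 matrix
#'   (rows = predicted/not, columns = under/not).
#' @return list with `table`, `odds_ratio` (conditional MLE), `p_value`,
#'   and `note` (non-`NULL` when a zero margin makes the table
#'   degenerate, in which case p = 1).
#' @export
enrichment_test <- function(report) {
  if (inherits(report, "tps_bin_report")) {
    tab <- matrix(c(report$interval$n_under,
                    report$interval$n_total - report$interval$n_under,
                    report$no_site$n_under,
                    report$no_site$n_total - report$no_site$n_under),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("predicted_in_interval", "no_site"),
                                  c("under", "not_under")))
  } else {
    tab <- as.matrix(report)
    stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1.0,
                note = "degenerate table (zero margin); p fixed at 1"))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, note = NULL)
}

#' Tally 5'-RLM-RACE clone ends against the predicted cleavage site
#'
#' RACE clones report the 5' end of the 3' cleavage fragment; the
#' canonical position is the transcript base paired to amiRNA position 10
#' ([predict_cleavage()]).
#'
#' @param clone_positions integer vector of clone 5'-end positions
#'   (1-based, on the hit's transcript).
#' @param hit one row of a [find_sites()] result.
#' @param max_tps optional eligibility cap on the hit's TPS (the Fig-8
#'   style preset uses 7: higher-scoring interactions are not expected to
#'   be cleaved). A hit above the cap is an error.
#' @return object of class `race_tally`: `positions` (data frame
#'   `position`, `count`), `canonical_position`, `canonical_fraction`
#'   (`NA` when no clones), `total`.
#' @export
race_tally <- function(clone_positions, hit, max_tps = NULL) {
  if (!is.null(max_tps) && hit$tps > max_tps)
    stop(sprintf("hit TPS %.1f exceeds RACE eligibility cap %.1f",
                 hit$tps, max_tps))
  canonical <- predict_cleavage(hit)
  clone_positions <- as.integer(clone_positions)
  total <- length(clone_positions)
  tab <- if (total) {
    t0 <- table(clone_positions)
    data.frame(position = as.integer(names(t0)), count = as.integer(t0))
  } else data.frame(position = integer(), count = integer())
  structure(list(positions = tab,
                 canonical_position = canonical,
                 canonical_fraction = if (total)
                   sum(clone_positions == canonical) / total else NA_real_,
                 total = total),
            class = "race_tally")
}

#' @export
print.race_tally <- function(x, ...) {
  cat(sprintf("<race_tally> %d clones; canonical position %d (%.0f%%)\n",
              x$total, x$canonical_position,
              100 * x$canonical_fraction))
  invisible(x)
}
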