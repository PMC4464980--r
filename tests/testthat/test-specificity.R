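test_that("DE status classification applies the q/log2fc rules and filters", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    log2fc = c(-2, -2, 2, -1, 0.5),
                    qvalue = c(0.001, 0.02, 0.005, NA, 0.0099))
  de <- classify_de(tab)
  expect_identical(as.character(de$status),
                   c("UNDER", "NS", "OVER", "NS", "OVER"))

  # DESeq2-dialect column names are accepted
  tab2 <- data.frame(gene_id = "g1", baseMean = 100,
                     log2FoldChange = -3, padj = 1e-5)
  expect_identical(as.character(classify_de(tab2)$status), "UNDER")

  expect_error(classify_de(rbind(tab, tab[1, ])), "duplicate")

  # zero-count pre-filter: a gene with 6/8 zero samples is dropped
  counts <- matrix(5, 5, 8, dimnames = list(tab$gene_id, NULL))
  counts["g2", 1:6] <- 0
  counts["g3", 1:4] <- 0
  de_f <- classify_de(tab, counts = counts)
  expect_false("g2" %in% de_f$gene_id)
  expect_true("g3" %in% de_f$gene_id)
})

test_that("classification is idempotent and threshold-monotone", {
  set.seed(170)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200),
                    qvalue = runif(200))
  thr <- sort(runif(6, 0.001, 0.9))
  prev_sig <- character(0)
  for (q in thr) {
    de <- classify_de(tab, q_threshold = q)
    sig <- de$gene_id[de$status != "NS"]
    expect_true(all(prev_sig %in% sig))  # sets grow with the threshold
    prev_sig <- sig
  }
})

test_that("TPS binning assigns per-gene minimum scores and closed-interval totals", {
  de <- classify_de(data.frame(gene_id = c("a", "b", "c"),
                               log2fc = c(-2, -2, 1),
                               qvalue = c(0.001, 0.5, 0.2)))
  hits <- data.frame(gene_id = c("a", "a", "b"), tps = c(3.5, 7, 4))
  rep_ <- bin_by_tps(de, hits)
  b35 <- rep_$bins[rep_$bins$bin == 3.5, ]
  expect_identical(b35$n_under, 1L)
  expect_identical(b35$n_total, 1L)
  expect_identical(rep_$bins[rep_$bins$bin == 7, ]$n_total, 0L)  # min taken
  expect_identical(rep_$interval$n_total, 1L)  # only b (tps 4) in [4,11]
  expect_identical(rep_$no_site$n_total, 1L)   # gene c

  # interval proportion = sum(under)/sum(total) over bins 4..11
  in_int <- rep_$bins[rep_$bins$bin >= 4 & rep_$bins$bin <= 11, ]
  expect_equal(rep_$interval$prop_under,
               sum(in_int$n_under) / sum(in_int$n_total))

  # hits for unknown genes warn and are skipped
  expect_warning(bin_by_tps(de, rbind(hits, data.frame(gene_id = "zz",
                                                       tps = 5))),
                 "zz")

  # binning is invariant to record order
  rep_rev <- bin_by_tps(de[3:1, ], hits[sample(3), ])
  expect_identical(rep_rev$bins, rep_$bins)
})

test_that("planted audit cohorts reproduce their generating bin counts exactly", {
  planted <- data.frame(
    tps = c(1, 3.5, 4, 4, 5.5, 7, 7, 9, 11, 11),
    status = c("UNDER", "NS", "UNDER", "NS", "OVER", "NS", "UNDER",
               "NS", "NS", "OVER"))
  sim <- simulate_audit(planted, n_no_site = 30, no_site_under = 3,
                        seed = 171)
  de <- classify_de(sim$de_table)
  # classification recovers the generating status per gene
  expect_identical(as.character(de$status[match(sim$truth$gene_id,
                                                de$gene_id)]),
                   sim$truth$status)
  rep_ <- bin_by_tps(de, sim$hits)
  for (b in unique(planted$tps)) {
    expect_identical(rep_$bins[rep_$bins$bin == b, ]$n_total,
                     sum(planted$tps == b))
    expect_identical(rep_$bins[rep_$bins$bin == b, ]$n_under,
                     sum(planted$tps == b & planted$status == "UNDER"))
  }
  expect_identical(rep_$no_site$n_total, 30L)
  expect_identical(rep_$no_site$n_under, 3L)
  expect_identical(rep_$interval$n_total, 8L)
  expect_identical(rep_$interval$n_under, 2L)
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  # identical proportions: p = 1
  expect_equal(enrichment_test(matrix(c(5, 95, 5, 95), 2,
                                      byrow = TRUE))$p_value, 1)
  # extreme association
  expect_lt(enrichment_test(matrix(c(0, 10, 10, 0), 2,
                                   byrow = TRUE))$p_value, 0.001)
  # degenerate margins
  deg <- enrichment_test(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_equal(deg$p_value, 1)
  expect_match(deg$note, "degenerate")

  # full enumeration for all tables with small margins
  for (r1 in c(1, 3, 6)) for (r2 in c(1, 4, 7)) {
    for (a in 0:r1) for (c_ in 0:r2) {
      tab <- matrix(c(a, r1 - a, c_, r2 - c_), 2, byrow = TRUE)
      if (any(colSums(tab) == 0)) next
      expect_equal(enrichment_test(tab)$p_value, oracle_fisher_p(tab),
                   tolerance = 1e-8)
    }
  }
  # random tables with margins up to 40
  set.seed(180)
  for (i in 1:200) {
    tab <- matrix(rbinom(4, 40, runif(1, 0.05, 0.5)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(enrichment_test(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-8)
  }
})

test_that("RACE tallies count canonical clone ends against the predicted site", {
  ami <- rand_amirna(190)
  tx <- paste0(rand_rna(100, seed = 191), revcomp(ami), rand_rna(30))
  hit <- find_sites(ami, c(t = tx))
  hit <- hit[hit$tps == 0, ]
  canon <- predict_cleavage(hit)
  expect_identical(canon, 112L)

  tal <- race_tally(c(rep(canon, 8), canon + 3, canon - 2), hit)
  expect_equal(tal$canonical_fraction, 0.8)
  expect_identical(tal$total, 10L)

  tal0 <- race_tally(rep(canon + 5, 4), hit)
  expect_equal(tal0$canonical_fraction, 0)

  tal_na <- race_tally(integer(0), hit)
  expect_identical(tal_na$total, 0L)
  expect_true(is.na(tal_na$canonical_fraction))

  # TPS <= 7 eligibility preset
  hit8 <- hit; hit8$tps <- 8
  expect_error(race_tally(canon, hit8, max_tps = 7), "eligibility")
  expect_silent(race_tally(canon, hit, max_tps = 7))

  # simulated 90/10 canonical/offset clones recover 0.9 within 3 SE
  set.seed(192)
  n <- 400
  clones <- ifelse(runif(n) < 0.9, canon, canon + 4)
  tal9 <- race_tally(clones, hit)
  expect_lt(abs(tal9$canonical_fraction - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})
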