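test_that("pair_class matches the hand-enumerated 4x4 truth table", {
  truth <- matrix("MISMATCH", 4, 4,
                  dimnames = list(c("A", "C", "G", "U"),
                                  c("A", "C", "G", "U")))
  truth["A", "U"] <- truth["U", "A"] <- "WATSON_CRICK"
  truth["G", "C"] <- truth["C", "G"] <- "WATSON_CRICK"
  truth["G", "U"] <- truth["U", "G"] <- "GU_WOBBLE"
  for (a in rownames(truth)) for (t in colnames(truth))
    expect_identical(pair_class(a, t), truth[a, t])
  expect_identical(pair_class("G", "T"), "GU_WOBBLE")  # DNA input
  expect_identical(pair_class("N", "A"), "MISMATCH")
  expect_error(pair_class("G", "X"), "non-nucleotide")
})

test_that("score_alignment applies penalties with core doubling", {
  wc <- rep("WATSON_CRICK", 21)
  expect_equal(score_alignment(duplex_alignment(wc)), 0)

  st <- wc; st[21] <- "MISMATCH"
  expect_equal(score_alignment(duplex_alignment(st)), 1)

  st <- wc; st[5] <- "GU_WOBBLE"
  expect_equal(score_alignment(duplex_alignment(st)), 1)  # 0.5 x 2 in core

  st <- wc; st[7] <- "AMIRNA_BULGE"
  expect_equal(score_alignment(duplex_alignment(st, "amirna", 7L)), 2)

  expect_equal(score_alignment(duplex_alignment(wc, "target", 5L)), 2)
  expect_equal(score_alignment(duplex_alignment(wc, "target", 20L)), 1)
})

test_that("core doubling and defect monotonicity hold over random alignments", {
  set.seed(201)
  core <- 2:13
  noncore <- c(1, 14:21)
  for (rep_i in 1:1000) {
    st <- sample(c("WATSON_CRICK", "GU_WOBBLE", "MISMATCH"), 21,
                 replace = TRUE, prob = c(0.7, 0.15, 0.15))
    base <- score_alignment(duplex_alignment(st))
    # score is always a multiple of 0.5
    expect_identical(base %% 0.5, 0)
    # same defect, core vs non-core position: exactly 2x
    i_core <- sample(core, 1); i_non <- sample(noncore, 1)
    for (defect in c("GU_WOBBLE", "MISMATCH")) {
      s1 <- st; s1[i_core] <- defect; s1[i_non] <- "WATSON_CRICK"
      s2 <- st; s2[i_non] <- defect; s2[i_core] <- "WATSON_CRICK"
      both_wc <- st; both_wc[c(i_core, i_non)] <- "WATSON_CRICK"
      d1 <- score_alignment(duplex_alignment(s1)) -
        score_alignment(duplex_alignment(both_wc))
      d2 <- score_alignment(duplex_alignment(s2)) -
        score_alignment(duplex_alignment(both_wc))
      expect_equal(d1, 2 * d2)
    }
    # degrading any single position never decreases the score
    j <- sample(1:21, 1)
    worse <- st
    worse[j] <- if (st[j] == "WATSON_CRICK") "GU_WOBBLE" else "MISMATCH"
    expect_gte(score_alignment(duplex_alignment(worse)), base)
  }
})

test_that("find_sites recovers a planted perfect complement at TPS 0", {
  ami <- rand_amirna(31)
  tx <- paste0(rand_rna(100, seed = 32), revcomp(ami), rand_rna(80))
  hits <- find_sites(ami, c(tx1 = tx))
  perfect <- hits[hits$tps == 0, ]
  expect_identical(nrow(perfect), 1L)
  expect_identical(perfect$start, 101L)
  expect_identical(perfect$end, 121L)
  expect_identical(perfect$alignment, paste(rep(":", 21), collapse = ""))
  expect_true(all(hits$tps <= 11))       # report cap
  expect_true(all(hits$tps %% 0.5 == 0)) # granularity
})

test_that("ungapped scan equals the exhaustive per-window oracle", {
  set.seed(41)
  for (case in 1:3) {
    ami <- rand_amirna(40 + case)
    tx <- rand_rna(500)
    hits <- find_sites(ami, c(t = tx), max_gaps = 0, cap = Inf)
    expect_identical(nrow(hits), 500L - 20L)
    oracle <- vapply(seq_len(500 - 20), function(s)
      oracle_window_tps(ami, substr(tx, s, s + 20)), numeric(1))
    got <- hits$tps[order(hits$start)]
    expect_equal(got, oracle)
    # and with the default cap, exactly the sub-threshold windows appear
    capped <- find_sites(ami, c(t = tx), max_gaps = 0)
    expect_identical(sort(capped$start), which(oracle <= 11))
  }
})

test_that("short transcripts yield an empty hit table", {
  ami <- rand_amirna(7)
  expect_identical(nrow(find_sites(ami, c(t = rand_rna(19, seed = 1)))), 0L)
  expect_identical(nrow(find_sites(ami, c(t = rand_rna(15, seed = 1)),
                                   max_gaps = 0)), 0L)
})

test_that("gapped alignments are found and scored with the bulge penalty", {
  ami <- rand_amirna(55)
  # target bulge: insert one extra base opposite the non-core 3' region
  site <- revcomp(ami)
  site_bulged <- paste0(substr(site, 1, 3), "A", substr(site, 4, 21))
  tx <- paste0(rand_rna(50, seed = 56), site_bulged, rand_rna(50))
  hits <- find_sites(ami, c(t = tx))
  tb <- hits[hits$gap_kind == "target" & hits$start == 51, ]
  expect_gte(nrow(tb), 1L)
  expect_equal(min(tb$tps), 1)  # bulge charged outside the core

  # amiRNA bulge: delete the target base opposite a non-core position
  site_del <- paste0(substr(site, 1, 3), substr(site, 5, 21))
  tx2 <- paste0(rand_rna(50, seed = 57), site_del, rand_rna(50))
  hits2 <- find_sites(ami, c(t = tx2))
  ab <- hits2[hits2$gap_kind == "amirna" & hits2$start == 51, ]
  expect_gte(nrow(ab), 1L)
  expect_equal(min(ab$tps), 1)
})

test_that("cleavage is predicted opposite amiRNA positions 10/11", {
  ami <- rand_amirna(61)
  tx <- paste0(rand_rna(100, seed = 62), revcomp(ami), rand_rna(30))
  hit <- find_sites(ami, c(t = tx))
  hit <- hit[hit$tps == 0, ]
  # site span 101..121: 3' fragment starts at 112 (bond between 111/112)
  expect_identical(predict_cleavage(hit), 112L)

  # offset case: site at span 1..21 cleaves between 11 and 12
  hit2 <- find_sites(ami, c(t = revcomp(ami)))
  hit2 <- hit2[hit2$tps == 0, ]
  expect_identical(predict_cleavage(hit2), 12L)

  # a bulge spanning the scissile bond is ambiguous
  fake <- data.frame(start = 1, end = 22, tps = 2, gap_kind = "target",
                     gap_pos = 11L)
  expect_error(predict_cleavage(fake), "ambiguous")
  fake2 <- data.frame(start = 1, end = 20, tps = 2, gap_kind = "amirna",
                      gap_pos = 10L)
  expect_error(predict_cleavage(fake2), "ambiguous")
})
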