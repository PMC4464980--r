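test_that("star strand follows the 2-nt 3'-overhang pairing register", {
  # all-A amiRNA with paired positions templated: U-rich complement
  ami_a <- paste(rep("A", 21), collapse = "")
  tmpl <- c("G", rep("pair", 18), "C", "A")
  star <- build_star(ami_a, tmpl)
  expect_identical(substr(star, 2, 19), paste(rep("U", 18), collapse = ""))
  expect_identical(substr(star, 1, 1), "G")

  # every templated "pair" position is Watson-Crick under the register
  # star position j pairs amiRNA position 20 - j
  for (seed in 1:5) {
    ami <- rand_amirna(seed)
    star <- build_star(ami)
    for (j in 2:19) {
      expect_identical(
        pair_class(substr(ami, 20 - j, 20 - j), substr(star, j, j)),
        "WATSON_CRICK")
    }
    expect_identical(substr(star, 1, 1), "G")
  }

  # positions without a partner cannot be templated "pair"
  expect_error(build_star(ami_a, rep("pair", 21)), "no amiRNA partner")
  expect_error(build_star(ami_a, c("G", rep("pair", 20))), "no amiRNA partner")
})

test_that("candidates are forced-U1/C19 reverse complements with at most two substitutions", {
  set.seed(71)
  tx <- rand_rna(80)
  cands <- candidates_from_target(tx)
  expect_length(cands, 80 - 20)
  for (cd in cands) {
    expect_identical(nchar(cd$amirna), 21L)
    expect_identical(substr(cd$amirna, 1, 1), "U")
    expect_identical(substr(cd$amirna, 19, 19), "C")
    expect_identical(substr(cd$star, 1, 1), "G")
    expect_true(all(unlist(cd$flags)))
    expect_lte(nrow(cd$substitutions), 2L)
    expect_true(all(cd$substitutions$position %in% c(1L, 19L)))
    expect_lte(cd$on_target_tps, 2)   # forced edits fall outside the core
    # non-substituted positions match the raw reverse complement
    raw <- revcomp(substr(tx, cd$source_window[1], cd$source_window[2]))
    keep <- setdiff(1:21, cd$substitutions$position)
    expect_identical(strsplit(cd$amirna, "")[[1]][keep],
                     strsplit(raw, "")[[1]][keep])
  }

  # a window whose reverse complement already starts U and has C19
  win <- revcomp(paste0("U", rand_rna(17, seed = 72), "C",
                        rand_rna(2)))
  cds <- candidates_from_target(win)
  expect_identical(nrow(cds[[1]]$substitutions), 0L)
  expect_equal(cds[[1]]$on_target_tps, 0)
})

test_that("design round-trip: every candidate's best site is its source window", {
  set.seed(73)
  tx <- rand_rna(60)
  for (cd in candidates_from_target(tx)) {
    hits <- find_sites(cd$amirna, c(target = tx))
    expect_lte(min(hits$tps), 2)
    expect_equal(min(hits$tps), cd$on_target_tps)
    src <- hits[hits$start == cd$source_window[1] &
                  hits$end == cd$source_window[2], ]
    expect_equal(min(src$tps), cd$on_target_tps)
  }
})

test_that("windows containing N are skipped with a note", {
  tx <- paste0(rand_rna(30, seed = 74), "N", rand_rna(30))
  expect_message(cands <- candidates_from_target(tx), "skipped")
  expect_length(cands, 61 - 20 - 21)  # windows covering the N are gone
})

test_that("assess_candidate applies the optimal criteria and strict off-target floor", {
  ami <- rand_amirna(81)
  target <- paste0(rand_rna(40, seed = 82), revcomp(ami), rand_rna(40))
  cand <- candidates_from_target(target)[[41]]  # the planted window
  expect_equal(cand$on_target_tps, 0)

  # intended transcript only: optimal
  rep1 <- assess_candidate(cand, "t1", c(t1 = target))
  expect_true(rep1$optimal)
  expect_identical(nrow(rep1$off_target_hits), 0L)

  # planted decoy at TPS 3: rejected
  txs <- simulate_transcriptome(cand$amirna, planted_tps = 3, seed = 83,
                                length = 120)
  rep2 <- assess_candidate(cand, "t1", c(t1 = target, decoy = txs[[1]]))
  expect_false(rep2$optimal)
  expect_true(any(grepl("decoy", rep2$rejection_reasons)))

  # decoy at exactly TPS 4: boundary is strict '< 4', still optimal
  txs4 <- simulate_transcriptome(cand$amirna, planted_tps = 4, seed = 84,
                                 length = 120)
  rep3 <- assess_candidate(cand, "t1", c(t1 = target, near = txs4[[1]]))
  expect_true(rep3$optimal)
  expect_true(any(rep3$off_target_hits$tps == 4))

  expect_error(assess_candidate(cand, "absent", c(t1 = target)), "absent")
})

test_that("design_amirnas ranks optimal candidates first, deterministically", {
  ami <- rand_amirna(91)
  target <- paste0(rand_rna(20, seed = 92), revcomp(ami), rand_rna(20))
  txome <- c(gene1 = target,
             bg = simulate_transcriptome(ami, background_n = 1,
                                         seed = 93, length = 100)[[1]])
  tab1 <- design_amirnas("gene1", txome, max_candidates = 5)
  tab2 <- design_amirnas("gene1", txome, max_candidates = 5)
  expect_identical(tab1, tab2)
  expect_true(all(diff(tab1$on_target_tps[tab1$optimal]) >= 0))
  expect_true(any(tab1$optimal))
})
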