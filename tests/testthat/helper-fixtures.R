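## Shared test fixtures, all built in code.

rand_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

## a random 21-nt amiRNA already satisfying the 5'U / C19 design rules
rand_amirna <- function(seed = 1) {
  set.seed(seed)
  x <- strsplit(rand_rna(21), "")[[1]]
  x[1] <- "U"
  x[19] <- "C"
  paste(x, collapse = "")
}

## synthetic hairpin: star arm + loop + mature arm (the 5' arm carries the
## star strand, which base-pairs the 3'-arm mature strand on foldback),
## with the annotation making the inter-arm segment exactly `loop_len` nt
synth_precursor <- function(id = "hp1", loop_len = 16, seed = 1,
                            flank = 10) {
  set.seed(seed)
  amirna <- rand_amirna(seed)
  star <- build_star(amirna)
  core <- paste0(star, rand_rna(loop_len), amirna)
  hp <- paste0(rand_rna(flank), core, rand_rna(flank))
  s0 <- flank
  precursor(id, hp,
            mature_span = c(s0 + 21 + loop_len + 1, s0 + 21 + loop_len + 21),
            star_span = c(s0 + 1, s0 + 21))
}

## independent brute-force TPS of one ungapped window (test-side oracle,
## no package scoring internals)
oracle_window_tps <- function(amirna, window, core = 2:13,
                              pen_mm = 1, pen_gu = 0.5, mult = 2) {
  a <- strsplit(chartr("T", "U", toupper(amirna)), "")[[1]]
  w <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  s <- 0
  for (i in 1:21) {
    t <- w[22 - i]
    p <- if (comp[[a[i]]] == t) 0
    else if ((a[i] == "G" && t == "U") || (a[i] == "U" && t == "G")) pen_gu
    else pen_mm
    s <- s + p * if (i %in% core) mult else 1
  }
  s
}

## exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
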