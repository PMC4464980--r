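# amirnaforge

Toolkit for engineering **artificial microRNAs (amiRNAs)** in plant
*MIR390* precursor backbones and auditing their specificity.

AmiRNAs are 21-nt small RNAs expressed from a natural *MIRNA* hairpin so
that DICER-LIKE1 processing releases a guide strand that silences one
chosen transcript. Designing them well requires several coordinated desk
computations, all implemented here:

* **Foldback anatomy** — distal stem–loop lengths of annotated hairpins
  (`precursor()`, `distal_loop()`, `anatomy_survey()`). The distal loop
  is the inter-arm segment; its length sets oligo synthesis cost.
* **Target Prediction Score (TPS)** — Allen/TargetFinder-style additive
  penalties over the 21 amiRNA positions: mismatch/bulge 1, G:U wobble
  0.5, doubled in the 5′ core (positions 2–13); lower = more
  complementary (`scoring_scheme()`, `score_alignment()`,
  `find_sites()`). Slicer cleavage is predicted opposite guide positions
  10/11 (`predict_cleavage()`).
* **Design** — P-SAMS-style candidates: reverse complement of each
  target window with forced 5′ U and C19; the amiRNA* strand pairs the
  guide under the 2-nt 3′-overhang register (star position *j* ↔ guide
  *20 − j*), giving the AGO-non-preferred star 5′ G. "Optimal" = on-target
  TPS ≤ 1 and no transcriptome interaction with TPS < 4
  (`candidates_from_target()`, `build_star()`, `assess_candidate()`,
  `design_amirnas()`).
* **Cloning oligos** — annealed oligonucleotide pairs with 5′-CTTG /
  5′-CATG overhangs for BsaI/ccdB ("B/c") vectors; 60-base oligos on the
  OsMIR390 template (16-nt loop), 44 + loop length in general
  (`load_templates()`, `assemble_insert()`, `emit_oligos()`,
  `screen_bsai()`).
* **Processing accuracy** — exact-match read stacks over a hairpin and
  the fraction of reads with both ends exactly matching the mature
  species (`map_reads()`, `processing_summary()`,
  `compare_precursors()`).
* **Specificity audit** — DE-status classification (q < 0.01), per-gene
  minimum-TPS binning with the [4, 11] off-target interval, two-sided
  Fisher exact enrichment, and 5′-RLM-RACE clone tallies against the
  canonical cleavage site (`classify_de()`, `bin_by_tps()`,
  `enrichment_test()`, `race_tally()`).
* **Pigments** — 80%-acetone chlorophyll/carotenoid formulas
  (`pigment_concentrations()`).
* **Simulators** — seed-deterministic reads, transcriptomes with sites
  planted at exact TPS values, and DE tables with planted UNDER sets
  (`simulate_reads()`, `simulate_transcriptome()`, `simulate_de()`,
  `simulate_audit()`).

## Worked example

Design amiRNAs against a transcript, emit cloning oligos for the
chimeric OsMIR390-AtL backbone, and locate the predicted cleavage site:

```r
library(amirnaforge)
# txome: named character vector with the intended target "BdGene1"
# plus background transcripts (here simulated; normally a transcriptome FASTA)
designs <- design_amirnas("BdGene1", txome, max_candidates = 3)
designs
#>                  amirna                  star window_start on_target_tps
#> 1 UGAGUGUGCCGUGCGCCACGA GUGGCGCACGGCACACUCACA           25             0
#> 2 UGGCCAUUAUCGCAAUCCCAG GGGAUUGCGAUAAUGGCCACA           58             0
#> 3 UAUAACGCAUCCAGUGGCCAU GGCCACUGGAUGCGUUAUACA           72             0
#>   n_offtargets_lt_floor worst_offtarget_tps optimal reasons
#> 1                     0                  NA    TRUE
#> 2                     0                  NA    TRUE
#> 3                     0                  NA    TRUE
```

Each row is a candidate: the 21-nt guide (5′ U, C19), its star strand
(5′ G), the target window it derives from, its on-target TPS (0 = perfect
complement after the forced edits) and the off-target verdict — `optimal`
means no transcriptome interaction scored below TPS 4.

```r
templates <- load_templates()
best <- designs[1, ]
ol <- emit_oligos(assemble_insert(best$amirna, best$star,
                                  templates$`OsMIR390-AtL`),
                  templates$`OsMIR390-AtL`)
ol
#> <oligo_pair> template OsMIR390-AtL (75/75 bases)
#>   F: 5'-CTTGTGAGTGTGCCGTGCGCCACGATATTCGTTATCTATTTTTGGATTTTCGATCTGTGGCGCACGGCACACTCA-3'
#>   R: 5'-CATGTGAGTGTGCCGTGCGCCACAGATCGAAAATCCAAAAATAGATAACGAATATCGTGGCGCACGGCACACTCA-3'

hits <- find_sites(best$amirna, txome["BdGene1"])
hits[1, c("start", "end", "tps", "alignment")]
#>   start end tps             alignment
#> 1    25  45   0 :::::::::::::::::::::
predict_cleavage(hits[1, ])
#> [1] 36
```

The two 75-base oligos (60 bases on the authentic OsMIR390 template)
anneal into a duplex with the 4-nt B/c overhangs; cleavage of the target
is predicted at position 36, the bond opposite guide positions 10/11 —
the coordinate at which 5′-RLM-RACE clone ends should accumulate
(`race_tally()` checks that against sequenced clones). The packaged
template file carries synthetic stand-in loop sequences (documented in
the methods vignette); substitute authentic precursor loops via
`load_templates(path = ...)` before ordering oligos.

Pigment quantification from a plate reading:

```r
pigment_concentrations(0.62, 0.24, 0.51)
#>    chl_a  chl_b carotenoid
#> 1 6.8958 1.7126   1.362733
```

## Documentation

The methods vignette (`vignettes/amirna-design-methods.Rmd`) documents
the scoring scheme and its conventions, the duplex register, the oligo
partition, what the simulators do and do not emulate, and known
limitations.
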