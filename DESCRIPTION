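Package: amirnaforge
Title: Design and Audit of Artificial microRNAs Expressed from MIR390-Based
    Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for engineering artificial microRNAs (amiRNAs) in plant
    MIR390 precursor backbones. Computes distal stem-loop anatomy of annotated
    MIRNA hairpins, scores amiRNA-target complementarity with an
    Allen/TargetFinder-style Target Prediction Score (TPS), designs optimal
    21-nt amiRNA/amiRNA* pairs against a background transcriptome, assembles
    the annealed-oligonucleotide inserts (with BsaI 'B/c' cloning overhangs)
    for OsMIR390- and AtMIR390a-derived precursor templates, profiles
    small-RNA read stacks to quantify precursor processing accuracy, audits
    genome-wide off-target specificity by TPS bin against differential
    expression calls, tallies 5'-RLM-RACE cleavage positions against the
    canonical slicer site, and evaluates spectrophotometric chlorophyll and
    carotenoid formulas. Seed-deterministic simulators generate reads,
    transcriptomes and differential-expression tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
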