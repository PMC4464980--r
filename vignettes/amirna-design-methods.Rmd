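---
title: "Methods: amiRNA design, scoring and auditing in MIR390 backbones"
author: "amirnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amiRNA design, scoring and auditing in MIR390 backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amirnaforge)
```

## Scope and model

An artificial microRNA (amiRNA) is a 21-nt guide strand engineered into a
plant *MIRNA* precursor so that DICER-LIKE1 releases an amiRNA/amiRNA*
duplex silencing a chosen transcript. This package covers the desk
computations of that workflow: precursor anatomy, target-site scoring,
candidate design, cloning-oligo assembly, small-RNA processing profiling,
and the genome-wide off-target audit. Everything operates on plain
sequences and tables; no secondary-structure prediction, alignment
heuristics or count-model fitting is performed here (DE tables are
consumed from upstream tools such as DESeq2, never produced).

## Foldback anatomy

A `precursor` is a hairpin sequence with 1-based inclusive mature and star
arm spans (the miRBase convention; converters to other coordinate systems
belong at I/O edges). The *distal stem--loop* is defined purely from the
annotation as the residues strictly between the two arms. This makes the
metric deterministic and invariant under T/U re-encoding, at the price of
ignoring any unpaired residues that structure prediction would assign to
the stem rather than the loop; since the quantity is used to compare
precursor backbones and to size cloning oligos, the annotation-based
definition is the appropriate one. Arms must be 19--24 nt, must not
overlap, and may not contain `N` (an `N` there would poison exact read
matching downstream; elsewhere in the hairpin it is tolerated).
`anatomy_survey()` reports the standard even/odd median and type-7
quantiles.

## Target Prediction Score

`score_alignment()` implements the additive Allen/TargetFinder penalty
scheme over the 21 amiRNA positions counted from the amiRNA 5' end:
mismatch and single-nucleotide bulge cost 1, a G:U wobble costs 0.5, and
each penalty is doubled when the amiRNA position lies in the 5' core
window (positions 2--13). Watson--Crick pairs cost 0. Lower TPS therefore
means higher complementarity; every score is a multiple of 0.5. All
constants live in `scoring_scheme()` and can be recalibrated without code
changes.

Numerical and convention choices:

* **Gapped alignment.** At most one single-nucleotide bulge is allowed
  (`max_gaps = 1`), found by trying each bulge placement explicitly
  rather than by dynamic programming -- O(21·L) per transcript and easy
  to verify exhaustively. Terminal bulge placements are excluded because
  they are coordinate shifts of ungapped windows.
* **Bulged target base.** A bulged target nucleotide occupies no amiRNA
  position; its penalty is charged at the amiRNA position immediately 3'
  of the insertion (so an insertion between positions 10 and 11 is
  charged, doubled, at position 11). This convention is documented
  because published tools do not print theirs.
* **Reporting.** Sites scoring above `report_cap` (default 11) are never
  emitted; per window start and bulge class the best placement is
  reported, overlapping windows are all reported, and hits sort by
  ascending TPS with ties by transcript and position. Only the mRNA
  sense strand is scanned. Transcript `N` scores as a mismatch; an
  amiRNA containing `N` is rejected.

`predict_cleavage()` returns the transcript base paired to amiRNA
position 10: slicer cuts the bond opposite positions 10/11, so the
returned coordinate is the 5' end of the 3' cleavage fragment -- exactly
where 5'-RLM-RACE clone ends accumulate. A bulge spanning the scissile
bond makes the site ambiguous and is an error rather than a guess.

## Candidate design

`candidates_from_target()` reconstructs the rational design procedure:
for each 21-nt target window the candidate is the reverse complement
with position 1 forced to `U` (AGO1-preferred 5' nucleotide) and
position 19 forced to `C`. Both forced positions lie outside the doubled
core, so a candidate's on-target TPS is at most 2 (0.5 per forced edit
that happens to create a wobble, 1 per mismatch). Acceptance of a design
("optimal") requires an on-target TPS of at most 1 and no other
transcriptome interaction below TPS 4 -- the published criterion states
"TPS = 1"; it is implemented as `on_target_tps <= 1` because a window
already carrying U1/C19 legitimately scores 0, and the strictly-equal
variant is available by setting `on_target_max`. The off-target floor is
strict (`< 4` rejects; a hit at exactly 4 does not).

The amiRNA* strand follows the canonical duplex register in which both
strands carry 2-nt 3' overhangs: star position *j* pairs amiRNA position
*20 − j*. Forcing amiRNA position 19 to `C` therefore places the
AGO-non-preferred `G` at star position 1, biasing loading toward the
guide strand. Star positions 20--21 have no guide partner; the default
template fixes them to `CA`, the residues the cloning overhang
regenerates at the vector junction (below). Structure-preserving
substitutions for a specific backbone are expressed as literal bases in
the duplex template, keeping the oligo module purely mechanical.

## Cloning oligonucleotides

Inserts for BsaI/ccdB ("B/c") vectors are two annealed oligonucleotides
with 4-nt 5' overhangs: forward `5'-CTTG`, reverse `5'-CATG`. Each oligo
carries amiRNA + distal loop + star positions 1--19; annealing gives a
perfect duplex flanked by the two overhangs, and because `CATG` is
palindromic its ligation regenerates the star 3'-overhang dinucleotide
`CA` on the coding strand at the vector junction. Oligo length is
therefore a template constant, 44 + loop length: 60 bases for the 16-nt
OsMIR390 distal loop, longer for AtMIR390a-loop templates. This
residue-level partition was reconstructed from the published overhang
and length constraints; the packaged template file accordingly carries
*synthetic* stand-in loop sequences (correct lengths, validated at load)
and a user template TSV can substitute authentic ones without code
changes. `screen_bsai()` flags internal `GGTCTC`/`GAGACC` hexamers,
which would be cut during cloning.

## Processing-accuracy profiling

`map_reads()` places each read at every exact sense-strand substring
match of the hairpin, crediting 1/k per locus for k-fold matches
(switchable to first-locus). Exact matching (0 mismatches) is chosen over
mismatch-tolerant alignment because hairpin-space precision, not
sensitivity, is what the processing metric needs. The stack matrix is
indexed by (5' position, length) for lengths 18--26 nt, the size classes
displayed in small-RNA read-stack figures; reads outside that window
count toward input but not toward the matrix. "Accurately processed"
requires *both* ends exact -- a 20-nt species sharing the mature 5' end is
not accurate, since length differences discriminate real processing
variants. With nothing mapped, fractions are reported `NA`, never 0.

## Specificity audit

`classify_de()` consumes a gene-level DE table (DESeq2 dialect accepted):
UNDER/OVER require adjusted p below the threshold (default 0.01, i.e. a
1% FDR) with the corresponding fold-change sign; anything else, including
missing q, is NS. An optional pre-filter drops genes with zero counts in
at least 5 of the provided samples (the 4-vs-4 comparison convention).
`bin_by_tps()` assigns each gene its minimum TPS over sites, bins at the
0.5 score granularity, and summarizes the closed interval [4, 11] -- the
only band in which an optimally designed amiRNA can have direct
off-targets. `enrichment_test()` contrasts genes predicted in that
interval against genes with no predicted site, using the two-sided Fisher
exact test in its standard sum-of-no-more-probable-tables definition (no
mid-p variant); a zero margin returns p = 1 with a degeneracy note
instead of failing. `race_tally()` compares RACE clone 5' ends with the
canonical cleavage coordinate and exposes the TPS ≤ 7 eligibility preset
used for cleavage assays (higher-scoring interactions are not expected to
be cleaved).

## Pigment formulas

`pigment_concentrations()` evaluates the 80%-acetone extinction
equations (chl a = 12.21·A663 − 2.81·A647; chl b = 20.13·A647 −
5.03·A663; carotenoid = (1000·A470 − 3.27·chl a − 104·chl b)/227), in
mg/L of extract, with an optional multiplicative dilution factor.
Negative outputs are reported as-is with a warning -- they are
informative about blank or scatter artifacts and silently clamping them
would bias comparisons.

## Synthetic-data generators

The simulators emulate the statistical structure of the data classes the
analysis modules consume, with every generating parameter recoverable:

* `simulate_reads()` draws the exact mature species with probability
  `fidelity` and otherwise a uniform (5' shift in ±3, length 18--26)
  off-register substring, resampling draws that leave the hairpin. The
  expected accurate fraction equals `fidelity` exactly.
* `simulate_transcriptome()` plants one site per transcript at an exact
  requested TPS by editing a perfect complement: non-core mismatches
  (+1), a non-core wobble (+0.5), core wobbles (+1) and core mismatches
  (+2), then *verifies by rescanning* that no gapped re-alignment
  undercuts the request, retrying otherwise. Wobble edits require a G or
  U at the edited amiRNA position, so a fractional TPS can be genuinely
  unreachable for wobble-free amiRNAs -- that is an error, not a silent
  approximation. Background transcripts are rejection-sampled to contain
  no reportable site.
* `simulate_de()` / `simulate_audit()` plant UNDER/OVER calls strictly
  inside, and null genes strictly outside, the q threshold, so
  classification and binning recover the generating counts exactly.

Each generator seeds its own RNG stream and restores the caller's state,
so adding a generator call never perturbs other fixtures. What the
simulators do **not** emulate: sequencing error, adapter artifacts,
expression-level count noise (negative-binomial dispersion), 3'
non-templated additions, and multi-locus genomic repeats. Passing the
recovery tests therefore demonstrates correctness of the bookkeeping and
estimators under clean conditions, not robustness to those real-data
features.

## Validation scales

The shipped test suite validates the scanner against an exhaustive
per-window oracle on 0.5--1 kb transcripts, score properties on 10^3
random alignments, fidelity recovery at depth 10^4 (within 3 binomial
standard errors), Fisher p-values against full hypergeometric enumeration
for table margins up to 40, and audit binning on planted cohorts of ~160
genes. These sizes keep the default run fast while leaving every check
exhaustive or statistically calibrated at its scale.

## Known limitations

* The distal-loop metric is annotation-driven; mis-annotated arms give
  mis-sized loops.
* TPS constants reproduce the published scheme's 1--11 range for 21-nt
  guides with ≤1 bulge, but corner conventions of specific external
  implementations (consecutive-mismatch caps, special position-1
  handling) are not modeled.
* The packaged template loop sequences are synthetic placeholders;
  cloning real constructs requires substituting authentic precursor
  loops via a user template file.
* One intended transcript per design run; multi-gene group targeting is
  out of scope.
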