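---
title: "Mining and mass-based verification of eight-cysteine hevein-like peptides"
author: "crpmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and mass-based verification of eight-cysteine hevein-like peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpmine)
```

# The biological problem

Ginsentide-like peptides are a subfamily of eight-cysteine hevein-like
peptides (8C-HLPs): ~33-residue, cysteine- and glycine-rich plant
peptides whose four disulfide bonds (Cys I–IV, II–VI, III–VII, V–VIII)
close a pseudocyclic, protease-resistant fold. Family members such as
the cocotides of cacao are found by sequence mining of transcriptomes
and verified by mass spectrometry rather than by direct sequencing:
their mass, their cysteine count (via the reduction/alkylation mass
shift), and their methionine-oxidation satellites are all diagnostic.
`crpmine` implements this mine-then-verify workflow, together with the
two-group enrichment filter used for downstream interactome experiments.

# The motif model

The scanner looks for the framework
`C Xn C Xn CC Xn C X C Xn C Xn C`: eight cysteines whose seven
intervening loops contain no cysteine, with the third loop empty (the
tandem `CC`). Because loops are cysteine-free, a framework necessarily
consists of eight *consecutive* cysteines of the sequence — the scanner
exploits this by sliding an 8-window over the cysteine positions, and
the test suite checks it against a brute-force enumeration over all
8-subsets of cysteine positions.

Loop-length bounds are a genuine modelling choice: the framework leaves
every `n` free, and unbounded loops would accept arbitrary cysteine
ladders. The defaults

| loop (between Cys k, k+1) | 1 | 2 | 3 (CC) | 4 (IV–V) | 5 (V–VI) | 6 | 7 |
|---------------------------|---|---|--------|----------|----------|---|---|
| min                       | 2 | 2 | 0      | 1        | 1        | 2 | 1 |
| max                       | 12| 12| 0      | 8        | 8        | 12| 10|

bracket the observed ginsentide/cocotide geometry — tC1's loop vector is
(6, 6, 0, 2, 1, 6, 4) — without admitting degenerate matches; all bounds
are configurable (`crpLoopBounds`). Note the numbering trap: the hevein
literature skips the empty CC gap, so its "loop 3" (Cys IV–V) is loop 4
in this package's consecutive numbering and its "loop 4" (Cys V–VI) is
loop 5. Reports carry positions, not loop numbers, to stay unambiguous.

Classification uses two rules. A framework is *ginsentide-like* when the
Cys V–VI loop is a single residue (the shortened `CXC` motif); it is
*chitin-binding* when the Cys IV–V loop contains the conserved
S-x-Φ-x-Φ domain (Φ ∈ {F, Y, W}) **and** the Cys V–VI loop has exactly
six residues including an aromatic. Everything else is `other_8C`. The
two rules are mutually exclusive (loop length 1 vs 6), and
classification is a function of the loop strings only, so it is
invariant to where the framework sits in the precursor.

Overlapping candidate frameworks are resolved greedily left to right
with no shared cysteines; this makes output deterministic. Matches whose
loops contain the ambiguity residue `X` are kept but flagged
low-confidence, since translated transcriptome contigs routinely contain
ambiguous codons.

# Precursor maturation

Ginsentide-like precursors are three-domain proteins: signal peptide,
prodomain, mature peptide. Maturation is modelled as asparaginyl
endopeptidase (AEP) cleavage at an Asn↓Cys junction chosen so that the
residue after the Asn is Cys I of a ginsentide-like framework; with the
default 26-residue signal and 35-residue prodomain of the synthetic
generator this reproduces cleavage between Asn61 and Cys62. When several
junctions qualify, the leftmost is used and alternatives are logged. The
mature peptide runs to the precursor's C-terminus by default, since only
the N-terminal maturation event is modelled.

Signal-peptide prediction is deliberately **not** re-implemented: the
field uses dedicated predictors, and the pipeline accepts their output
as a per-sequence `signalEnd`. When absent, a Kyte–Doolittle fallback
(longest window of ≥8 residues with mean hydropathy > 1.5 within the
first 40 residues; cleavage 5 residues after its end) produces an
*approximate* boundary explicitly flagged `"heuristic"`. The AEP
donor/acceptor sets are configurable (`donors = c("N","D")` for relaxed
AEP specificity in other CRP families).

# Mass arithmetic

All mass constants live in one internal table: monoisotopic and average
residue masses, water (18.010565 / 18.0153 Da), the proton
(1.007276 Da), carbamidomethylation (+57.02146 Da per Cys), methionine
sulfoxide (+15.99491 Da, nominal 16), and the two hydrogens exchanged
per disulfide (2.01565 Da). A native peptide with `k` disulfides weighs
`sum(residues) + water − k × 2.01565`. The unit suite cross-checks the
monoisotopic table against an independent elemental-composition route
(residue formulas × atomic masses) for five residues.

Two consequences worth spelling out:

* the reduction + carbamidomethylation shift of an `n`-Cys, `s`-disulfide
  peptide is `n × 57.02146 + s × 2.01565` — for the 8-Cys/4-SS framework
  this is 464.23 Da (nominal **464**), i.e. ~58 Da per cysteine when
  fully bonded, not the 56 Da sometimes quoted from the alkylation step
  alone;
* `inferCysCount` inverts this relation to count cysteines from an
  observed MALDI shift, with ties toward the smaller count and an
  explicit "ambiguous shift" error when no count lies within tolerance.

Nominal-Da reports round half away from zero (`nominalDa`), matching how
integer shifts are conventionally quoted. An average-mass table is
included because linear-mode MALDI of 3+ kDa species may effectively
report average masses; monoisotopic is the default, and the native tC1
mass satisfies the 3.3–3.4 kDa family range on either scale.

# Peak matching and oxidation fractions

MS1 peak lists are plain two-column text (m/z, intensity). Proteoform
ladders enumerate Met(O) states 0..min(maxOx, #Met), optionally on the
reduced/alkylated backbone. Matching assigns each proteoform the nearest
peak within `max(tolDa, tolPpm × m/z / 1e6)`; the defaults
(0.5 Da, 200 ppm) reflect externally calibrated linear-mode MALDI
accuracy at ~3 kDa — the much tighter 10 ppm figure belongs to orbitrap
LC-MS/MS workflows, not MALDI screening. Ties between equidistant peaks
go to the higher-intensity, then lower-m/z peak; a peak serving several
proteoforms is flagged ambiguous.

Oxidation fractions are computed molecule-level: the matched intensity
of the k-oxidized form over the total matched intensity of that peptide,
summing to 1. Attributing oxidation to a *specific* methionine (e.g.
position 9 vs 13 vs 25) requires MS2 site localization, which is outside
this package's scope; outputs say so.

# Differential quantification

The enrichment filter is the conventional volcano rule: a protein passes
when its treatment/control change is at least 2-fold
(`|log2 fc| ≥ 1`) with significance > 15 on the −10·log10(p) scale
(p < 10^−1.5 ≈ 0.032). Since the proprietary significance metric of
common proteomics software is unpublished, `proteinStats` implements a
documented approximation: a two-sided Welch t-test on log2-transformed,
pseudocount-guarded intensities. No multiple-testing correction is
applied by default because the filter operates on raw significance; a
Benjamini–Hochberg option exists (`adjust = "BH"`). Proteins with fewer
than two finite values in a group are excluded and reported rather than
imputed. Fold changes are computed as differences of group means on the
log2 scale, which makes the whole statistic invariant to global
intensity rescaling.

One statistical subtlety is documented rather than hidden: at 3 vs 3
replicates the Welch test is **conservative**. With equal group sizes
the Welch statistic equals the pooled-variance statistic, but its
Welch–Satterthwaite degrees of freedom are a random quantity ≤ 4, so
null p-values are stochastically larger than uniform. A direct
simulation of the test puts its true size at α = 10^−1.5 near 0.021
rather than the nominal 0.032; the test suite asserts exactly this
behaviour (empirical null rate within Monte-Carlo error of an
independently simulated reference size, and conservative with respect to
nominal). Users who want nominal calibration at n = 3/3 should use a
pooled test; the Welch form is kept because unequal variances between
pull-down and control channels are the rule in enrichment designs.

# The synthetic-data generators

The generators produce the three data classes the pipeline consumes,
each with a truth table sufficient to score every downstream stage, and
each a pure function of the seed.

* **Transcriptomes** (`simulateTranscriptome`): 12 planted precursor
  transcripts (one per family member) and 50 random-codon decoys by
  default. Planted precursors have a Met-initiated hydrophobic
  26-residue signal, a cysteine-free 35-residue prodomain ending in Asn
  (placing the junction at Asn61/Cys62), and a mature domain derived
  from the tC1 template by substitutions at a 5% per-residue rate at
  non-Cys positions — never touching a cysteine and never introducing
  one, mirroring the family's absolute Cys conservation and keeping
  planted members ~90% identical to the template, in line with the
  85–90% similarity typical within the family. Back-translation draws
  uniformly over synonymous codons (codon bias is irrelevant to the
  stages under test), and half the planted transcripts are
  reverse-complemented to exercise both strands.
* **Peak lists** (`simulatePeakList`): each peptide contributes its
  [M+H]⁺ peak with 50 ppm Gaussian mass error and — when it contains
  Met — a mono-oxidized satellite at +15.9949 Da whose intensity ratio
  encodes a planted 27% oxidized fraction; planted intensities carry 5%
  lognormal noise, and 30 uniform low-intensity noise peaks populate the
  2–5 kDa window.
* **Quant matrices** (`simulateQuant`): log2 intensities
  Normal(baseline, 0.1) at 3 vs 3 samples, with a chosen fraction of
  proteins shifted by log2 fc = 2 in the treatment group.

What the generators do *not* emulate — isotope envelopes, detector
saturation, retention-time structure, correlated protein baselines,
missing-value mechanisms of real label-free data — bounds what passing
tests show: they validate the algorithms' correctness and calibration
under the stated statistical model, not instrument-level realism.

# Numerical and design choices

* Coordinates are 1-based inclusive in every user-visible output
  (matching residue conventions like "Asn61/Cys62"); internal arithmetic
  is plain integer indexing.
* Percent compositions round half-up at one decimal; nominal masses
  round half away from zero.
* Percent identity is ungapped for equal-length pairs; unequal-length
  pairs use a global alignment (match 1, mismatch 0, linear gap 1) via
  `Biostrings::pairwiseAlignment`, reported as 100 × matches / alignment
  length. The metric is labelled *identity* throughout — similarity
  under substitution groups is a different, unimplemented statistic.
* ORFs are Met-initiated and stop-terminated by default (both
  relaxable); a trailing segment without a stop codon is not reported.
* Degenerate diffquant rows (zero variance in both groups) get p = 1 at
  equal means; equal-mean groups therefore never pass the filter.
* Problem sizes in the test suite and acceptance script — exhaustive
  scanner checks to length 12 plus seeded 200-mers, 5 × 1000-protein
  null simulations, 20 replicate spectra, 12 planted precursors — were
  chosen as the smallest sizes at which Monte-Carlo error is negligible
  relative to the tested tolerances.

# Known limitations

* The motif scanner is a grammar matcher, not a homology search: remote
  family members with a ninth cysteine or an expanded loop outside the
  configured bounds will be missed.
* The signal-peptide heuristic is a flagged fallback, not a predictor;
  supply external predictions for real annotation work.
* Site-level Met(O) localization, MS2 scoring, isotope-cluster
  deconvolution and peptide-to-protein inference are out of scope.
* The Welch-based significance is an approximation of proprietary
  software scales; absolute significance values will differ from such
  tools even when the ranking largely agrees.
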