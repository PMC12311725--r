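# crpmine

Discovery and mass-spectrometric characterization of eight-cysteine
hevein-like peptides (8C-HLPs) in R.

Plants such as ginseng, coffee and cacao produce compact, hyperstable
cysteine-rich peptides of ~30–40 residues whose eight cysteines form four
disulfide bonds in the conserved pattern Cys I–IV, II–VI, III–VII, V–VIII,
closing a pseudocyclic fold. The ginsentide-like subfamily (which includes
the cocotides of *Theobroma cacao*) is recognized in sequence data by the
cysteine framework

```
C X(n1) C X(n2) CC X(n3) C X C X(n4) C X(n5) C
```

— a tandem `CC` plus a shortened one-residue `CXC` loop between Cys V and
Cys VI — whereas chitin-binding 8C-HLPs instead carry a conserved
S-x-Φ-x-Φ domain (Φ aromatic) in the Cys IV–V loop and a six-residue
Cys V–VI loop. These peptides are synthesized as three-domain precursors
(signal peptide, prodomain, mature domain) and released by asparaginyl
endopeptidase (AEP) cleavage at an Asn↓Cys junction, so the mature peptide
begins at Cys I.

`crpmine` packages the complete desk-side workflow around these peptides:

* **seqio** — FASTA I/O, six-frame translation, ORF finding
  (`readFasta`, `sixFrameTranslate`, `findOrfs`);
* **motif engine** — framework scanning, subfamily classification,
  disulfide-connectivity assignment, identity and composition statistics
  (`scanCrpMotif`, `classify8cHlp`, `assignConnectivity`,
  `pairwiseIdentity`, `computeComposition`);
* **precursor model** — AEP-site detection and mature-peptide excision
  (`findAepSites`, `parsePrecursor`, `exciseMature`);
* **mass arithmetic** — disulfide-aware monoisotopic/average masses and
  modification-shift algebra: carbamidomethylation (+57.02146 Da/Cys),
  disulfide reduction (+2.01565 Da/bond), Met(O) (+15.99491 Da), plus the
  inverse problem of counting cysteines from an observed
  reduction/alkylation shift (`peptideMass`, `modificationShift`,
  `reductionAlkylationShift`, `inferCysCount`, `massToMz`);
* **peak matching** — MS1 peak-list parsing, Met(O) proteoform ladders,
  tolerance-based matching, 2–5 kDa window screening, and molecule-level
  oxidation-fraction estimation (`readPeakList`, `enumerateOxoforms`,
  `matchPeaks`, `screenWindow`, `oxidationFraction`);
* **differential quantification** — two-group fold-change / Welch
  significance analysis with the volcano filter (≥2-fold,
  significance −10·log10 p > 15) and contaminant exclusion
  (`quantMatrix`, `proteinStats`, `volcanoFilter`,
  `excludeContaminants`);
* **synthetic data** — seeded generators for decoy transcriptomes with
  planted precursors, MALDI-like peak lists, and two-group quant matrices,
  each with a ground-truth table (`simConfig`, `simulateTranscriptome`,
  `simulatePeakList`, `simulateQuant`);
* **pipelines** — the composed discovery and enrichment workflows with
  YAML-serializable configuration (`pipelineConfig`, `runDiscovery`,
  `runEnrichment`).

## Worked example

The 33-residue cacao peptide tC1 is bundled as `tc1Sequence()`:

```r
library(crpmine)

m <- scanCrpMotif(tc1Sequence(), sourceId = "tC1")[[1]]
m
#> MotifMatch in 'tC1'
#>   Cys I-VIII at: 1, 8, 15, 16, 19, 21, 28, 33
#>   loop lengths : 6,6,0,2,1,6,4

classify8cHlp(m)
#> CRPClass: ginsentide_like
#>   evidence: cysV_VI_loop_length_1_CXC

assignConnectivity(m)
#>   romanPair pos1 pos2
#> 1      I-IV    1   16
#> 2     II-VI    8   21
#> 3   III-VII   15   28
#> 4    V-VIII   19   33

peptideMass(tc1Sequence(), nDisulfides = 4)   # native [M], monoisotopic
#> [1] 3368.128
nominalDa(reductionAlkylationShift(8, 4))     # S-reduction + alkylation
#> [1] 464
comp <- computeComposition(tc1Sequence())
c(comp$percents[["C"]], comp$percents[["G"]], comp$netFormalCharge)
#> [1] 24.2 21.2 -1.0
```

Reading the output: the scanner finds exactly one eight-cysteine
framework whose single-residue Cys V–VI loop marks it ginsentide-like;
the fixed connectivity maps the four disulfides onto residues
(1,16)(8,21)(15,28)(19,33); the four-disulfide monoisotopic mass is
3368.13 Da (3.37 kDa, [M+H]⁺ 3369.14); fully reducing and
carbamidomethylating its 8 cysteines adds a nominal 464 Da — the mass
shift by which cysteine content is counted in a MALDI experiment; and
the peptide is Cys/Gly-rich (24.2% / 21.2%) with a net formal charge of
−1.

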