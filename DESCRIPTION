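Package: crpmine
Title: Discovery and Mass-Spectrometric Characterization of
    Eight-Cysteine Hevein-Like Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mining ginsentide-like cysteine-rich peptides
    (8C-HLPs) from transcriptome or protein sequence data and verifying
    them by MALDI-TOF mass spectrometry. Implements six-frame translation
    and ORF finding, a scanner for the eight-cysteine CXnCXnCCXnCXCXnCXnC
    framework with ginsentide-like versus chitin-binding classification
    and fixed disulfide connectivity assignment, three-domain precursor
    modeling with asparaginyl-endopeptidase (Asn-Cys) maturation,
    disulfide-aware monoisotopic and average mass arithmetic with
    carbamidomethylation and methionine-sulfoxide shift algebra, MS1
    peak-list matching and oxidation-proteoform fraction estimation, and
    two-group fold-change/significance enrichment filtering with
    contaminant exclusion for affinity-enrichment and TMT proteomics.
    A synthetic-data module generates transcriptomes with planted
    precursors, MALDI-like peak lists, and quantification matrices with
    ground-truth tables so every stage can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
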