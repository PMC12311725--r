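test_that("scanner finds the single tC1 framework with the expected geometry", {
  mm <- scanCrpMotif(TC1, sourceId = "tC1")
  expect_length(mm, 1)
  m <- mm[[1]]
  expect_equal(cysPositions(m), c(1L, 8L, 15L, 16L, 19L, 21L, 28L, 33L))
  expect_equal(loopLengths(m), c(6L, 6L, 0L, 2L, 1L, 6L, 4L))
  expect_equal(loopSeqs(m)[3], "")
  expect_false(m@lowConfidence)
  expect_equal(motifSpan(m), c(1L, 33L))
})

test_that("degenerate cysteine runs and short sequences yield no match", {
  expect_length(scanCrpMotif("CCCCCCCC"), 0)
  expect_length(scanCrpMotif("ACDEFG"), 0)
  # X inside a loop flags the match low-confidence
  seqX <- sub("LSAGGF", "LSXGGF", TC1)
  mmx <- scanCrpMotif(seqX)
  expect_length(mmx, 1)
  expect_true(mmx[[1]]@lowConfidence)
})

test_that("scanner agrees with the brute-force subset oracle", {
  # exhaustive over all {C,A} strings up to length 12, with loop bounds
  # tightened so frameworks fit in that length
  tight <- crpLoopBounds(min = c(0, 0, 0, 0, 0, 0, 0),
                         max = c(2, 2, 0, 2, 2, 2, 2))
  for (len in 8:12) {
    grid <- expand.grid(rep(list(c("C", "A")), len),
                        stringsAsFactors = FALSE)
    seqs <- do.call(paste0, grid)
    # fewer than 8 cysteines can never match: check a thinned sample of
    # those, compare every string that could match
    nC <- nchar(gsub("A", "", seqs))
    for (s in seqs[nC < 8][seq(1, sum(nC < 8), by = 97)])
      expect_length(scanCrpMotif(s, bounds = tight), 0)
    candidates <- seqs[nC >= 8]
    got <- lapply(candidates, function(s)
      lapply(scanCrpMotif(s, bounds = tight), cysPositions))
    want <- lapply(candidates, bruteForceMotif, bounds = tight)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("scanner matches the oracle on random 200-mers at default bounds", {
  set.seed(7)
  bounds <- crpLoopBounds()
  for (rep in 1:30) {
    s <- randomProteinFewCys(200, sample(8:14, 1))
    got <- lapply(scanCrpMotif(s, bounds = bounds), cysPositions)
    want <- bruteForceMotif(s, bounds)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("classification separates ginsentide-like from chitin-binding", {
  # tC1: Cys V-VI loop is the single residue G -> ginsentide-like
  cls <- classify8cHlp(scanCrpMotif(TC1)[[1]])
  expect_equal(crpLabel(cls), "ginsentide_like")
  expect_true(length(classEvidence(cls)) > 0)

  # constructed chitin-binding framework: loop IV-V carries S-x-Phi-x-Phi,
  # loop V-VI has six residues with an aromatic
  chitin <- "CAAGGFACAAGGFACCASAYAYCAAYAAACAAGGFACGGGGC"
  mm <- scanCrpMotif(chitin)
  expect_length(mm, 1)
  expect_equal(crpLabel(classify8cHlp(mm[[1]])), "chitin_binding_8C_HLP")

  # neither rule: three-residue loop V-VI, no SxPhixPhi
  other <- "CAAGGFACAAGGFACCAGNCAGACAAGGFACGGGGC"
  mo <- scanCrpMotif(other)
  expect_length(mo, 1)
  expect_equal(crpLabel(classify8cHlp(mo[[1]])), "other_8C")
})

test_that("classification depends only on loop strings (shift invariance)", {
  shifted <- paste0("AAAAA", TC1)
  a <- scanCrpMotif(TC1)[[1]]
  b <- scanCrpMotif(shifted)[[1]]
  expect_equal(cysPositions(b), cysPositions(a) + 5L)
  expect_equal(crpLabel(classify8cHlp(a)), crpLabel(classify8cHlp(b)))
  expect_equal(loopSeqs(a), loopSeqs(b))
})

test_that("connectivity maps the fixed I-IV/II-VI/III-VII/V-VIII pairing", {
  m <- scanCrpMotif(TC1)[[1]]
  conn <- assignConnectivity(m)
  expect_equal(conn$pos1, c(1L, 8L, 15L, 19L))
  expect_equal(conn$pos2, c(16L, 21L, 28L, 33L))
  # perfect matching on the eight cysteines
  expect_setequal(c(conn$pos1, conn$pos2), cysPositions(m))
  # translation invariance
  conn2 <- assignConnectivity(scanCrpMotif(paste0("GGG", TC1))[[1]])
  expect_equal(conn2$pos1, conn$pos1 + 3L)
  expect_equal(conn2$pos2, conn$pos2 + 3L)
})

test_that("pairwise identity follows the match-count arithmetic", {
  expect_equal(pairwiseIdentity(TC1, TC1), 100)
  # one substitution in a 33-mer
  one <- sub("^CLS", "CLA", TC1)
  expect_equal(pairwiseIdentity(TC1, one), 100 * 32 / 33, tolerance = 1e-9)
  # two substitutions
  two <- sub("GSGC$", "GAGA", TC1)
  expect_equal(pairwiseIdentity(TC1, two), 100 * 31 / 33, tolerance = 1e-9)
  # symmetry, including the gapped unequal-length branch
  expect_equal(pairwiseIdentity("MKVAA", "MKV"),
               pairwiseIdentity("MKV", "MKVAA"))
  expect_error(pairwiseIdentity("", "MKV"), "non-empty")
})

test_that("composition counts, percents and net charge are exact for tC1", {
  comp <- computeComposition(TC1)
  expect_equal(comp$length, 33L)
  expect_equal(comp$counts[["C"]], 8L)
  expect_equal(comp$counts[["G"]], 7L)
  expect_equal(comp$counts[["M"]], 3L)
  expect_equal(comp$percents[["C"]], 24.2)
  expect_equal(comp$percents[["G"]], 21.2)
  expect_equal(comp$netFormalCharge, -1L)
  expect_equal(sum(comp$counts), comp$length)

  g <- computeComposition("G")
  expect_equal(g$length, 1L)
  expect_equal(g$percents[["G"]], 100)
  expect_error(computeComposition("MKZ"), "position")
})

test_that("composition percents sum to 100 within rounding", {
  set.seed(3)
  for (rep in 1:20) {
    s <- randomProtein(sample(5:80, 1),
                       alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    comp <- computeComposition(s)
    expect_lt(abs(sum(comp$percents) - 100), 1.1)  # 20 residues x 0.05
  }
})
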