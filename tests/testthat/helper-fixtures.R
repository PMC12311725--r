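# Shared fixtures. TC1 is the printed 33-residue mature peptide the
# analytic checks rest on (eight Cys, seven Gly, three Met).
TC1 <- "CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC"

# tC1 monoisotopic reference masses, frozen from an independent
# elemental-composition computation (residue formulas x atomic masses).
TC1_MASS_0SS <- 3376.1909
TC1_MASS_4SS <- 3368.1283
TC1_MH_4SS   <- 3369.1356

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Brute-force motif oracle: enumerate every 8-subset of cysteine positions,
# keep those whose seven gaps are cysteine-free and within bounds, then
# apply the same greedy left-to-right non-overlap rule as the scanner.
# Independent of the scanner's consecutive-cysteine shortcut.
bruteForceMotif <- function(seq, bounds) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cys <- which(chars == "C")
  if (length(cys) < 8L) return(list())
  combos <- utils::combn(cys, 8L, simplify = FALSE)
  ok <- Filter(function(pos) {
    gaps <- diff(pos) - 1L
    if (any(gaps < bounds[, "min"]) || any(gaps > bounds[, "max"]))
      return(FALSE)
    # loops must be cysteine-free
    for (k in 1:7) {
      if (gaps[k] > 0L &&
          any(chars[(pos[k] + 1L):(pos[k + 1L] - 1L)] == "C"))
        return(FALSE)
    }
    TRUE
  }, combos)
  if (!length(ok)) return(list())
  # greedy left-to-right, no shared cysteine
  ok <- ok[order(vapply(ok, `[`, integer(1), 1L),
                 vapply(ok, `[`, integer(1), 8L))]
  chosen <- list()
  used <- integer()
  for (pos in ok) {
    if (!any(pos %in% used)) {
      chosen[[length(chosen) + 1L]] <- pos
      used <- c(used, pos)
    }
  }
  chosen
}

randomProtein <- function(n, alphabet = c("C", "A", "G", "S", "M", "F")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random sequence with a bounded cysteine count, so the 8-subset oracle
# stays tractable (combn(nCys, 8) subsets).
randomProteinFewCys <- function(n, nCys) {
  chars <- sample(c("A", "G", "S", "M", "F"), n, replace = TRUE)
  chars[sample(n, nCys)] <- "C"
  paste(chars, collapse = "")
}
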