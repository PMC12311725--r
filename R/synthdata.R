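## The mature-domain template used by the generator: the 33-residue,
## eight-cysteine, ginsentide-like peptide most abundant in cacao bean
## extracts (tC1).
.TC1 <- "CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC"

#' The tC1 mature-peptide template
#'
#' Returns the 33-residue eight-cysteine ginsentide-like peptide used as
#' the generator's mature-domain template.
#' @return named character scalar.
#' @export
tc1Sequence <- function() c(tC1 = .TC1)

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' Defaults encode the study conditions the pipeline is meant for: 12
#' planted precursor transcripts (one per family member), a 26-residue
#' signal peptide and 35-residue prodomain so that cleavage falls at
#' Asn61/Cys62, a 5\% non-cysteine substitution rate that keeps planted
#' family members ~90\% identical to the template, 50 ppm MALDI mass
#' noise, a 27\% mono-oxidized fraction, and 3 vs 3 quantification groups.
#'
#' @param seed integer seed; mandatory for every stochastic routine.
#' @param nDecoys random-codon decoy transcripts.
#' @param nPlanted planted precursor transcripts.
#' @param mutationRate per-residue substitution probability at non-Cys
#'   positions of the mature template.
#' @param signalLen,proLen signal-peptide and prodomain lengths (residues);
#'   the prodomain's last residue is Asn.
#' @param massNoisePpm 1-sigma relative mass error of simulated peaks, ppm.
#' @param oxFraction planted mono-oxidized (Met(O)) molecule fraction.
#' @param intensityCv multiplicative (lognormal) coefficient of variation
#'   applied to planted peak intensities.
#' @param nNoisePeaks low-intensity uniform noise peaks per spectrum.
#' @param quant list: \code{nProteins}, \code{nPlantedUp},
#'   \code{plantedLog2fc}, \code{noiseSd}, \code{groupSizes} (length 2).
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed, nDecoys = 50L, nPlanted = 12L,
                      mutationRate = 0.05, signalLen = 26L, proLen = 35L,
                      massNoisePpm = 50, oxFraction = 0.27,
                      intensityCv = 0.05, nNoisePeaks = 30L,
                      quant = list(nProteins = 1000L, nPlantedUp = 0L,
                                   plantedLog2fc = 2, noiseSd = 0.1,
                                   groupSizes = c(3L, 3L))) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            nDecoys >= 0, nPlanted >= 0,
            mutationRate >= 0, mutationRate <= 1,
            signalLen >= 8, proLen >= 2,
            massNoisePpm >= 0, oxFraction >= 0, oxFraction < 1,
            intensityCv >= 0, nNoisePeaks >= 0,
            quant$nProteins >= 1, quant$nPlantedUp >= 0,
            quant$nPlantedUp <= quant$nProteins,
            quant$noiseSd > 0, length(quant$groupSizes) == 2L,
            all(quant$groupSizes >= 2L))
  cfg <- list(seed = as.integer(seed), nDecoys = as.integer(nDecoys),
              nPlanted = as.integer(nPlanted),
              mutationRate = mutationRate,
              signalLen = as.integer(signalLen),
              proLen = as.integer(proLen),
              massNoisePpm = massNoisePpm, oxFraction = oxFraction,
              intensityCv = intensityCv,
              nNoisePeaks = as.integer(nNoisePeaks), quant = quant)
  class(cfg) <- "SimConfig"
  cfg
}

## uniform synonymous back-translation of one protein sequence
.backTranslate <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  codonsByAa <- split(names(gc), gc)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(a) {
    cs <- codonsByAa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

## mature-template mutagenesis: substitutions at non-Cys positions only,
## never introducing a cysteine, so the 8-Cys framework stays intact
.mutateMature <- function(template, rate) {
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  mutable <- which(chars != "C")
  hit <- mutable[runif(length(mutable)) < rate]
  for (i in hit) {
    alt <- setdiff(.AA20, c("C", chars[i]))
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Simulate a decoy transcriptome with planted CRP precursors
#'
#' Generates \code{nDecoys} random-codon decoy transcripts plus
#' \code{nPlanted} transcripts each encoding a three-domain precursor:
#' Met-initiated hydrophobic signal peptide (\code{signalLen}), random
#' prodomain ending in Asn (\code{proLen}), and a mature domain derived
#' from the tC1 template by non-Cys substitutions at \code{mutationRate},
#' followed by a stop codon. Signal and prodomain are cysteine-free so the
#' planted Asn-Cys junction is unique. A random half of the planted
#' transcripts is reverse-complemented. Fully deterministic given
#' \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{transcripts} (\code{DNAStringSet}) and
#'   \code{truth} (data.frame: id, planted, strand, signalEnd, aepSite,
#'   matureStart, matureSeq; NA fields for decoys).
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, {
    hydrophobic <- c("L", "A", "V", "I", "F", "W", "M")
    proPool <- setdiff(.AA20, "C")
    planted <- lapply(seq_len(cfg$nPlanted), function(i) {
      signal <- paste0("M", paste(sample(hydrophobic, cfg$signalLen - 1L,
                                         replace = TRUE), collapse = ""))
      pro <- paste0(paste(sample(proPool, cfg$proLen - 1L, replace = TRUE),
                          collapse = ""), "N")
      mature <- .mutateMature(.TC1, cfg$mutationRate)
      protein <- paste0(signal, pro, mature)
      dna <- paste0(.backTranslate(protein),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      list(id = sprintf("planted_%02d", i), protein = protein,
           mature = mature, dna = dna)
    })
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    decoys <- lapply(seq_len(cfg$nDecoys), function(i) {
      nCodon <- sample(60:150, 1L)
      list(id = sprintf("decoy_%03d", i),
           dna = paste(sample(sense, nCodon, replace = TRUE),
                       collapse = ""))
    })
    strands <- rep("+", cfg$nPlanted)
    if (cfg$nPlanted > 1L) {
      flip <- sample(cfg$nPlanted, cfg$nPlanted %/% 2L)
      strands[flip] <- "-"
    }
    seqs <- character(); ids <- character()
    for (k in seq_along(planted)) {
      d <- planted[[k]]$dna
      if (strands[k] == "-")
        d <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(d)))
      seqs <- c(seqs, d); ids <- c(ids, planted[[k]]$id)
    }
    for (d in decoys) { seqs <- c(seqs, d$dna); ids <- c(ids, d$id) }
    transcripts <- Biostrings::DNAStringSet(seqs)
    names(transcripts) <- ids
    aep <- cfg$signalLen + cfg$proLen
    truth <- data.frame(
      id = ids,
      planted = c(rep(TRUE, cfg$nPlanted), rep(FALSE, cfg$nDecoys)),
      strand = c(strands, rep(NA_character_, cfg$nDecoys)),
      signalEnd = c(rep(cfg$signalLen, cfg$nPlanted),
                    rep(NA_integer_, cfg$nDecoys)),
      aepSite = c(rep(aep, cfg$nPlanted), rep(NA_integer_, cfg$nDecoys)),
      matureStart = c(rep(aep + 1L, cfg$nPlanted),
                      rep(NA_integer_, cfg$nDecoys)),
      matureSeq = c(vapply(planted, `[[`, character(1), "mature"),
                    rep(NA_character_, cfg$nDecoys)),
      stringsAsFactors = FALSE)
    list(transcripts = transcripts, truth = truth)
  })
}

#' Simulate a MALDI-like MS1 peak list for a set of peptides
#'
#' For each peptide, plants the singly protonated [M+H]+ peak of the
#' 4-disulfide form with multiplicative Gaussian mass error
#' (sigma = \code{massNoisePpm}), and -- when the peptide contains Met and
#' \code{oxFraction > 0} -- a mono-oxidized satellite at +15.99491 Da with
#' intensity ratio \code{oxFraction / (1 - oxFraction)} to the base peak;
#' planted intensities carry multiplicative lognormal noise
#' (\code{intensityCv}). Adds \code{nNoisePeaks} uniform low-intensity
#' noise peaks in the
#' 2-5 kDa neutral-mass window. Deterministic given \code{cfg$seed}.
#'
#' @param peptides named character vector (or \code{AAStringSet}) of mature
#'   peptide sequences.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{peaks} (a \linkS4class{PeakList}) and
#'   \code{truth} (data.frame: mz, intensity, kind, baseId, nMetOx).
#' @export
simulatePeakList <- function(peptides, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (methods::is(peptides, "XStringSet"))
    peptides <- setNames(as.character(peptides), names(peptides))
  if (is.null(names(peptides)))
    names(peptides) <- sprintf("pep_%02d", seq_along(peptides))
  withr::with_seed(cfg$seed, {
    rows <- list()
    for (id in names(peptides)) {
      seq <- peptides[[id]]
      nSS <- min(4L, sum(strsplit(seq, "")[[1L]] == "C") %/% 2L)
      m <- peptideMass(seq, nDisulfides = nSS)
      baseInt <- runif(1, 500, 1000)
      mzTrue <- massToMz(m)
      mzObs <- mzTrue * (1 + rnorm(1, 0, cfg$massNoisePpm * 1e-6))
      jitter <- function() exp(rnorm(1, 0, cfg$intensityCv))
      rows[[length(rows) + 1L]] <- data.frame(
        mz = mzObs, intensity = baseInt * (1 - cfg$oxFraction) * jitter(),
        kind = "base", baseId = id, nMetOx = 0L, stringsAsFactors = FALSE)
      hasMet <- grepl("M", seq, fixed = TRUE)
      if (cfg$oxFraction > 0 && hasMet) {
        mzSat <- massToMz(m + .MOD_SHIFTS$met_oxidation[["monoisotopic"]])
        mzSatObs <- mzSat * (1 + rnorm(1, 0, cfg$massNoisePpm * 1e-6))
        rows[[length(rows) + 1L]] <- data.frame(
          mz = mzSatObs, intensity = baseInt * cfg$oxFraction * jitter(),
          kind = "satellite", baseId = id, nMetOx = 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (cfg$nNoisePeaks > 0L) {
      noiseFloor <- if (length(rows)) {
        0.05 * min(vapply(rows, function(r) r$intensity[1L], numeric(1)))
      } else 10
      rows[[length(rows) + 1L]] <- data.frame(
        mz = runif(cfg$nNoisePeaks, 2000, 5000) + .PROTON,
        intensity = runif(cfg$nNoisePeaks, 0, noiseFloor),
        kind = "noise", baseId = NA_character_, nMetOx = NA_integer_,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$mz), ]
    rownames(truth) <- NULL
    list(peaks = peakList(truth$mz, truth$intensity,
                          source = "synthetic spectrum"),
         truth = truth)
  })
}

#' Simulate a two-group protein quantification matrix
#'
#' Log2 intensities are Normal(baseline_i, noiseSd) per protein and
#' sample, with the first \code{nPlantedUp} proteins shifted upward by
#' \code{plantedLog2fc} in the treatment group; baselines are uniform on
#' log2 [18, 24]. Returned intensities are on the raw (2^x) scale.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}} (fields under \code{cfg$quant}).
#' @return list with \code{se} (a \code{SummarizedExperiment} from
#'   \code{\link{quantMatrix}}) and \code{truth} (data.frame: protein,
#'   planted, trueLog2fc).
#' @export
simulateQuant <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  q <- cfg$quant
  withr::with_seed(cfg$seed, {
    nC <- q$groupSizes[1L]; nT <- q$groupSizes[2L]
    n <- q$nProteins
    baseline <- runif(n, 18, 24)
    lx <- matrix(rnorm(n * (nC + nT), mean = baseline, sd = q$noiseSd),
                 nrow = n)
    if (q$nPlantedUp > 0L)
      lx[seq_len(q$nPlantedUp), nC + seq_len(nT)] <-
        lx[seq_len(q$nPlantedUp), nC + seq_len(nT)] + q$plantedLog2fc
    vals <- 2^lx
    rownames(vals) <- sprintf("P%04d", seq_len(n))
    colnames(vals) <- c(sprintf("ctrl_%d", seq_len(nC)),
                        sprintf("trt_%d", seq_len(nT)))
    se <- quantMatrix(vals, c(rep("control", nC), rep("treatment", nT)))
    truth <- data.frame(
      protein = rownames(vals),
      planted = seq_len(n) <= q$nPlantedUp,
      trueLog2fc = ifelse(seq_len(n) <= q$nPlantedUp, q$plantedLog2fc, 0),
      stringsAsFactors = FALSE)
    list(se = se, truth = truth)
  })
}
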