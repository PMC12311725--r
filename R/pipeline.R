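#' Pipeline configuration
#'
#' Collects every tunable of the discovery and enrichment workflows in one
#' serializable list. Unspecified entries keep their defaults; the
#' fully-resolved configuration (plus its hash and the package version) is
#' stamped into every output file header, so identical configurations
#' produce identical outputs.
#'
#' @param inputFasta path to the input FASTA (contigs or proteins).
#' @param inputKind \code{"nucleotide"} or \code{"protein"}.
#' @param peakListPath optional MS1 peak list to match candidates against.
#' @param signalTsv optional TSV (id, signalEnd) of precomputed
#'   signal-peptide cleavage positions from an external predictor.
#' @param minOrf minimum ORF length (residues).
#' @param loopMin,loopMax per-loop bounds for \code{\link{crpLoopBounds}}.
#' @param classFilter report only this subfamily (\code{"ginsentide_like"},
#'   \code{"chitin_binding_8C_HLP"}, \code{"other_8C"}, or \code{"all"}).
#' @param nDisulfides disulfide count for predicted native masses.
#' @param scale mass scale.
#' @param tolDa,tolPpm peak-match tolerances.
#' @param windowLo,windowHi neutral-mass screening window (Da).
#' @param quantMatrixPath,groupsPath,contaminantsPath enrichment inputs:
#'   intensity matrix TSV, one-line group map TSV, contaminant id list.
#' @param pseudocount,minFc,minSig enrichment-filter parameters.
#' @param seed integer seed recorded in output headers.
#' @param outDir output directory.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(inputFasta = NULL,
                           inputKind = c("nucleotide", "protein"),
                           peakListPath = NULL, signalTsv = NULL,
                           minOrf = 60L,
                           loopMin = c(2L, 2L, 0L, 1L, 1L, 2L, 1L),
                           loopMax = c(12L, 12L, 0L, 8L, 8L, 12L, 10L),
                           classFilter = "ginsentide_like",
                           nDisulfides = 4L,
                           scale = c("monoisotopic", "average"),
                           tolDa = 0.5, tolPpm = 200,
                           windowLo = 2000, windowHi = 5000,
                           quantMatrixPath = NULL, groupsPath = NULL,
                           contaminantsPath = NULL,
                           pseudocount = 1, minFc = 2, minSig = 15,
                           seed = 1L, outDir = ".") {
  cfg <- list(inputFasta = inputFasta, inputKind = match.arg(inputKind),
              peakListPath = peakListPath, signalTsv = signalTsv,
              minOrf = as.integer(minOrf),
              loopMin = as.integer(loopMin), loopMax = as.integer(loopMax),
              classFilter = classFilter,
              nDisulfides = as.integer(nDisulfides),
              scale = match.arg(scale), tolDa = tolDa, tolPpm = tolPpm,
              windowLo = windowLo, windowHi = windowHi,
              quantMatrixPath = quantMatrixPath, groupsPath = groupsPath,
              contaminantsPath = contaminantsPath,
              pseudocount = pseudocount, minFc = minFc, minSig = minSig,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / deserialize a pipeline configuration
#'
#' YAML round-trip of a \code{\link{pipelineConfig}}; reading re-applies
#' the constructor so the round-trip is lossless and validated.
#'
#' @param cfg a \code{PipelineConfig}.
#' @param path YAML file path.
#' @return \code{writeConfig}: the path, invisibly; \code{readConfig}: a
#'   \code{PipelineConfig}.
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(pipelineConfig, raw)
}

.cfgHeader <- function(cfg) {
  ## outDir does not influence results, only where they land
  fp <- unclass(cfg)
  fp$outDir <- NULL
  h <- .configHash(paste(deparse(fp), collapse = ""))
  c(paste0("config-hash: ", h),
    paste0("seed: ", cfg$seed),
    paste0("crpmine version: ",
           as.character(utils::packageVersion("crpmine"))))
}

## Candidate mature peptides from one protein sequence: precursor parsing
## first; sequences that are already mature (framework starting anywhere,
## no qualifying AEP site) are taken as-is.
.candidatesFromProtein <- function(seq, id, cfg, signalEnds) {
  bounds <- crpLoopBounds(cfg$loopMin, cfg$loopMax)
  sigEnd <- if (!is.null(signalEnds) && id %in% names(signalEnds))
    signalEnds[[id]] else NULL
  model <- tryCatch(
    parsePrecursor(seq, signalEnd = sigEnd, bounds = bounds,
                   sourceId = id),
    error = function(e) NULL)
  if (!is.null(model))
    return(list(mature = matureSeq(model), sourceId = id,
                origin = "precursor", aepSite = aepSite(model)))
  mm <- scanCrpMotif(seq, bounds = bounds, sourceId = id)
  if (length(mm))
    return(list(mature = seq, sourceId = id, origin = "as_is",
                aepSite = NA_integer_))
  NULL
}

#' Run the discovery workflow
#'
#' The composed mining pipeline: read sequences (six-frame translate and
#' ORF-scan when nucleotide), locate eight-cysteine frameworks, classify
#' them, excise mature peptides at the Asn-Cys AEP site, and report
#' composition, predicted masses (native [M], [M+H]+, reduced+alkylated,
#' Met(O) oxoforms) and -- when a peak list is supplied -- MS1 matches.
#'
#' @param cfg a \code{\link{pipelineConfig}} with at least
#'   \code{inputFasta} set.
#' @return the candidate report \code{data.frame}, invisibly; writes
#'   \code{candidates.tsv} (and \code{peak_matches.tsv} when applicable)
#'   under \code{cfg$outDir}.
#' @export
runDiscovery <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(cfg$inputFasta)) stop("config error: inputFasta is required")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  bounds <- crpLoopBounds(cfg$loopMin, cfg$loopMax)

  signalEnds <- NULL
  if (!is.null(cfg$signalTsv)) {
    sig <- utils::read.table(cfg$signalTsv, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    signalEnds <- setNames(as.list(as.integer(sig[[2L]])), sig[[1L]])
  }

  seqs <- readFasta(cfg$inputFasta, kind = cfg$inputKind)
  proteins <- character(); pids <- character()
  if (cfg$inputKind == "nucleotide") {
    for (i in seq_along(seqs)) {
      frames <- sixFrameTranslate(seqs[i])
      orfs <- findOrfs(frames, minLen = cfg$minOrf)
      proteins <- c(proteins, as.character(orfs))
      pids <- c(pids, names(orfs))
    }
  } else {
    proteins <- as.character(seqs)
    pids <- sub("\\s.*$", "", names(seqs))
  }

  rows <- list()
  for (i in seq_along(proteins)) {
    cand <- .candidatesFromProtein(proteins[i], pids[i], cfg, signalEnds)
    if (is.null(cand)) next
    mm <- scanCrpMotif(cand$mature, bounds = bounds,
                       sourceId = cand$sourceId)
    if (!length(mm)) next
    cls <- classify8cHlp(mm[[1L]])
    if (cfg$classFilter != "all" && crpLabel(cls) != cfg$classFilter)
      next
    comp <- computeComposition(cand$mature)
    nCys <- comp$counts[["C"]]
    nSS <- min(cfg$nDisulfides, nCys %/% 2L)
    massNative <- peptideMass(cand$mature, nDisulfides = nSS,
                              scale = cfg$scale)
    conn <- assignConnectivity(mm[[1L]])
    rows[[length(rows) + 1L]] <- data.frame(
      sourceId = cand$sourceId, origin = cand$origin,
      aepSite = cand$aepSite, matureSeq = cand$mature,
      length = comp$length, nCys = nCys, nGly = comp$counts[["G"]],
      cysPercent = comp$percents[["C"]], glyPercent = comp$percents[["G"]],
      netCharge = comp$netFormalCharge,
      class = crpLabel(cls),
      evidence = paste(classEvidence(cls), collapse = ";"),
      loopLengths = paste(loopLengths(mm[[1L]]), collapse = ","),
      connectivity = paste(sprintf("(%d,%d)", conn$pos1, conn$pos2),
                           collapse = ""),
      massNative = round(massNative, 4),
      mhPlus = round(massToMz(massNative), 4),
      massReducedAlkylated = round(
        massNative + reductionAlkylationShift(nCys, nSS), 4),
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sourceId = character(), origin = character(),
               aepSite = integer(), matureSeq = character(),
               length = integer(), nCys = integer(), nGly = integer(),
               cysPercent = numeric(), glyPercent = numeric(),
               netCharge = integer(), class = character(),
               evidence = character(), loopLengths = character(),
               connectivity = character(), massNative = numeric(),
               mhPlus = numeric(), massReducedAlkylated = numeric(),
               stringsAsFactors = FALSE)
  if (!nrow(report)) warning("no candidates found in ", cfg$inputFasta)
  hdr <- .cfgHeader(cfg)
  .writeTsv(report, file.path(cfg$outDir, "candidates.tsv"), hdr)

  if (!is.null(cfg$peakListPath) && nrow(report)) {
    pl <- screenWindow(readPeakList(cfg$peakListPath),
                       lo = cfg$windowLo, hi = cfg$windowHi)
    forms <- do.call(rbind, lapply(seq_len(nrow(report)), function(i)
      enumerateOxoforms(report$matureSeq[i], report$sourceId[i],
                        nDisulfides = min(cfg$nDisulfides,
                                          report$nCys[i] %/% 2L),
                        scale = cfg$scale)))
    matches <- matchPeaks(pl, forms, tolDa = cfg$tolDa,
                          tolPpm = cfg$tolPpm)
    .writeTsv(matches, file.path(cfg$outDir, "peak_matches.tsv"), hdr)
    attr(report, "peakMatches") <- matches
  }
  invisible(report)
}

#' Run the enrichment workflow
#'
#' The composed two-group comparison: read the intensity matrix and group
#' map, compute per-protein fold change and Welch significance, apply the
#' fold-change/significance volcano filter, and optionally exclude
#' contaminants from the enriched list.
#'
#' The group-map TSV has one row per sample: \code{sample<TAB>group} with
#' group \code{control} or \code{treatment}.
#'
#' @param cfg a \code{\link{pipelineConfig}} with \code{quantMatrixPath}
#'   and \code{groupsPath} set.
#' @return list with \code{stats}, \code{enriched}, \code{depleted},
#'   \code{removedContaminants}, invisibly; writes \code{protein_stats.tsv},
#'   \code{enriched.txt}, \code{depleted.txt} under \code{cfg$outDir}.
#' @export
runEnrichment <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(cfg$quantMatrixPath) || is.null(cfg$groupsPath))
    stop("config error: quantMatrixPath and groupsPath are required")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  vals <- as.matrix(utils::read.table(cfg$quantMatrixPath, header = TRUE,
                                      sep = "\t", row.names = 1L,
                                      check.names = FALSE))
  gm <- utils::read.table(cfg$groupsPath, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(gm) < 2L || !all(colnames(vals) %in% gm[[1L]]))
    stop("config error: malformed group map (need sample<TAB>group rows ",
         "covering every matrix column)")
  groups <- setNames(gm[[2L]], gm[[1L]])[colnames(vals)]
  se <- quantMatrix(vals, groups)
  stats <- proteinStats(se, pseudocount = cfg$pseudocount)
  filt <- volcanoFilter(stats, minFc = cfg$minFc, minSig = cfg$minSig)
  enriched <- filt$enriched
  removed <- character()
  if (!is.null(cfg$contaminantsPath)) {
    excl <- excludeContaminants(enriched,
                                readContaminants(cfg$contaminantsPath))
    enriched <- excl$kept
    removed <- excl$removed
  }
  hdr <- .cfgHeader(cfg)
  .writeTsv(filt$stats, file.path(cfg$outDir, "protein_stats.tsv"), hdr)
  writeLines(c(paste0("# ", hdr), enriched),
             file.path(cfg$outDir, "enriched.txt"))
  writeLines(c(paste0("# ", hdr), filt$depleted),
             file.path(cfg$outDir, "depleted.txt"))
  invisible(list(stats = filt$stats, enriched = enriched,
                 depleted = filt$depleted,
                 removedContaminants = removed))
}
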