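#' Construct a PeakList
#'
#' @param mz numeric vector of m/z values.
#' @param intensity numeric vector of non-negative intensities.
#' @param source free-text provenance.
#' @return a \linkS4class{PeakList}, sorted by ascending m/z.
#' @export
peakList <- function(mz = numeric(), intensity = numeric(),
                     source = "in-memory") {
  stopifnot(length(mz) == length(intensity))
  o <- order(mz)
  methods::new("PeakList",
               peaks = data.frame(mz = as.numeric(mz[o]),
                                  intensity = as.numeric(intensity[o])),
               source = source)
}

#' Read an MS1 peak list from two-column text
#'
#' Parses a whitespace- or comma-delimited two-column text file of
#' (m/z, intensity). A single non-numeric header line is tolerated; blank
#' lines and lines starting with \code{#} are skipped. Peaks are sorted by
#' ascending m/z on load.
#'
#' @param path path to the peak-list file.
#' @return a \linkS4class{PeakList}.
#' @export
readPeakList <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) {
    warning("empty peak list: ", path)
    return(peakList(source = path))
  }
  mzs <- numeric(); ints <- numeric()
  first <- TRUE
  for (i in keep) {
    fields <- strsplit(trimws(lines[i]), "[,\\s]+", perl = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      if (first) { first <- FALSE; next }  # tolerated header line
      stop("non-numeric field in peak list at line ", i, ": ", lines[i])
    }
    first <- FALSE
    if (length(vals) < 2L)
      stop("expected two columns in peak list at line ", i)
    mzs <- c(mzs, vals[1L]); ints <- c(ints, vals[2L])
  }
  if (!length(mzs)) {
    warning("empty peak list: ", path)
    return(peakList(source = path))
  }
  peakList(mzs, ints, source = path)
}

#' Write a PeakList as two-column text
#'
#' @param pl a \linkS4class{PeakList}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePeakList <- function(pl, path) {
  stopifnot(methods::is(pl, "PeakList"))
  utils::write.table(pl@peaks, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Enumerate methionine-oxidation proteoforms
#'
#' Builds the ladder of Met(O) proteoforms of a peptide: oxidation counts 0
#' to \code{min(maxOx, number of Met)}, each adding +15.99491 Da. The
#' native (disulfide-bonded) or reduced/alkylated backbone is controlled by
#' \code{nDisulfides} and \code{alkylated}; an alkylated form carries one
#' carbamidomethyl per cysteine and no disulfides.
#'
#' @param x peptide sequence.
#' @param baseId identifier for the peptide; defaults to its name.
#' @param nDisulfides disulfide bonds of the base form; default
#'   \code{NULL} = fully bonded up to the framework's four
#'   (\code{min(4, floor(nCys/2))}).
#' @param maxOx maximum oxidation count (default \code{Inf} = all Met).
#' @param alkylated logical; fully reduced and S-carbamidomethylated form.
#' @param charge charge state for the reported m/z (default 1, [M+H]+).
#' @param scale mass scale.
#' @return a \code{data.frame} with columns \code{baseId}, \code{seq},
#'   \code{nDisulfides}, \code{nMetOx}, \code{alkylated}, \code{mass},
#'   \code{mz}; masses strictly increasing in \code{nMetOx}.
#' @export
#' @examples
#' f <- enumerateOxoforms("CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC", "tC1")
#' diff(f$mass)  # 15.99491 spacing, 4 proteoforms (3 Met)
enumerateOxoforms <- function(x, baseId = NULL, nDisulfides = NULL,
                              maxOx = Inf, alkylated = FALSE, charge = 1L,
                              scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  if (is.null(baseId)) baseId <- .seqId(x, "peptide")
  seq <- .asSeqChar(x)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  nMet <- sum(chars == "M")
  nCys <- sum(chars == "C")
  if (is.null(nDisulfides)) nDisulfides <- min(4L, nCys %/% 2L)
  if (alkylated) nDisulfides <- 0L
  kmax <- min(maxOx, nMet)
  base <- peptideMass(seq, nDisulfides = nDisulfides, scale = scale)
  if (alkylated)
    base <- base + modificationShift(c(carbamidomethyl = nCys), scale)
  k <- 0:kmax
  mass <- base + k * .MOD_SHIFTS$met_oxidation[[scale]]
  baseId <- unname(baseId)
  data.frame(baseId = baseId, seq = seq, nDisulfides = nDisulfides,
             nMetOx = k, alkylated = alkylated, mass = mass,
             mz = massToMz(mass, charge), stringsAsFactors = FALSE)
}

#' Match proteoforms against an MS1 peak list
#'
#' Matches each proteoform to the nearest peak within tolerance. The
#' effective tolerance at a given m/z is \code{max(tolDa, tolPpm * mz /
#' 1e6)} -- the default 0.5 Da / 200 ppm reflects externally calibrated
#' linear-mode MALDI accuracy around 3 kDa. Ties between equidistant peaks
#' go to the higher-intensity, then lower-m/z peak. A peak may satisfy
#' several proteoforms; such ambiguous assignments are flagged with a
#' warning and an \code{ambiguous} column.
#'
#' @param pl a \linkS4class{PeakList}.
#' @param forms proteoform table from \code{\link{enumerateOxoforms}} (or
#'   any data.frame with \code{baseId}, \code{nMetOx}, \code{mz}).
#' @param tolDa absolute tolerance in Da (> 0).
#' @param tolPpm relative tolerance in ppm (> 0).
#' @return a \code{data.frame} of matches: \code{baseId}, \code{nMetOx},
#'   \code{theoreticalMz}, \code{observedMz}, \code{intensity},
#'   \code{errorDa}, \code{errorPpm}, \code{ambiguous}. Zero rows when
#'   nothing matches.
#' @export
matchPeaks <- function(pl, forms, tolDa = 0.5, tolPpm = 200) {
  stopifnot(methods::is(pl, "PeakList"), tolDa > 0, tolPpm > 0)
  pk <- pl@peaks
  empty <- data.frame(baseId = character(), nMetOx = integer(),
                      theoreticalMz = numeric(), observedMz = numeric(),
                      intensity = numeric(), errorDa = numeric(),
                      errorPpm = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(pk) || !nrow(forms)) return(empty)
  rows <- vector("list", nrow(forms))
  for (i in seq_len(nrow(forms))) {
    target <- forms$mz[i]
    tol <- max(tolDa, tolPpm * target / 1e6)
    d <- abs(pk$mz - target)
    inTol <- which(d <= tol)
    if (!length(inTol)) next
    ## nearest; ties -> higher intensity, then lower m/z
    o <- inTol[order(d[inTol], -pk$intensity[inTol], pk$mz[inTol])]
    j <- o[1L]
    rows[[i]] <- data.frame(
      baseId = forms$baseId[i], nMetOx = forms$nMetOx[i],
      theoreticalMz = target, observedMz = pk$mz[j],
      intensity = pk$intensity[j], errorDa = pk$mz[j] - target,
      errorPpm = (pk$mz[j] - target) / target * 1e6,
      ambiguous = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  dup <- duplicated(out$observedMz) | duplicated(out$observedMz,
                                                fromLast = TRUE)
  out$ambiguous <- dup
  if (any(dup))
    warning(sum(dup), " match(es) share a peak with another proteoform ",
            "(ambiguous assignment)")
  rownames(out) <- NULL
  out
}

#' Restrict a peak list to a neutral-mass window
#'
#' Keeps singly protonated peaks whose neutral mass (m/z - 1.007276) lies
#' in [lo, hi] and whose intensity reaches \code{minRelIntensity} times the
#' in-window maximum. The 2-5 kDa window is where cysteine-rich peptides
#' cluster in MALDI profiles of plant extracts.
#'
#' @param pl a \linkS4class{PeakList}.
#' @param lo,hi neutral-mass window bounds in Da (lo < hi).
#' @param minRelIntensity fraction of the in-window maximum intensity below
#'   which peaks are dropped (0 keeps all).
#' @return a filtered \linkS4class{PeakList}.
#' @export
screenWindow <- function(pl, lo = 2000, hi = 5000, minRelIntensity = 0) {
  stopifnot(methods::is(pl, "PeakList"), lo < hi,
            minRelIntensity >= 0, minRelIntensity <= 1)
  pk <- pl@peaks
  neutral <- pk$mz - .PROTON
  inWin <- neutral >= lo & neutral <= hi
  pk <- pk[inWin, , drop = FALSE]
  if (nrow(pk) && minRelIntensity > 0)
    pk <- pk[pk$intensity >= minRelIntensity * max(pk$intensity), ,
             drop = FALSE]
  peakList(pk$mz, pk$intensity, source = paste0(pl@source, " [window]"))
}

#' Molecule-level methionine-oxidation fractions
#'
#' From matched oxoform peaks of one or more base peptides, estimates the
#' fraction of each oxidation level as its matched intensity over the total
#' matched intensity of that peptide. Fractions sum to 1 per peptide.
#' These are molecule-level proteoform fractions; attributing oxidation to
#' a specific Met site requires MS2 localization, which this package does
#' not do.
#'
#' @param matches match table from \code{\link{matchPeaks}}.
#' @return a \code{data.frame} with columns \code{baseId}, \code{nMetOx},
#'   \code{fraction}.
#' @export
#' @examples
#' pl <- peakList(c(3369.135, 3385.130), c(73, 27))
#' f <- enumerateOxoforms("CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC", "tC1")
#' oxidationFraction(matchPeaks(pl, f))  # f(1) = 0.27
oxidationFraction <- function(matches) {
  if (!nrow(matches)) stop("no matches: oxidation fraction undefined")
  out <- do.call(rbind, lapply(split(matches, matches$baseId), function(g) {
    tot <- sum(g$intensity)
    if (tot <= 0)
      stop("zero total intensity for '", g$baseId[1L],
           "': oxidation fraction undefined")
    data.frame(baseId = g$baseId[1L], nMetOx = g$nMetOx,
               fraction = g$intensity / tot, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
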