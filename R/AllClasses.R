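#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' One eight-cysteine CRP framework occurrence
#'
#' A single hit of the CXnCXnCCXnCXCXnCXnC eight-cysteine framework in a
#' protein sequence. Cysteines are numbered Cys I-VIII left to right;
#' \code{loops} holds the seven inter-cysteine segments (the third, between
#' the tandem CC, is always empty). Coordinates are 1-based residue indices
#' in the scanned sequence.
#'
#' @slot sourceId identifier of the scanned sequence.
#' @slot cysPositions integer(8), strictly increasing 1-based positions of
#'   Cys I-VIII.
#' @slot loops character(7), segments between consecutive framework
#'   cysteines; \code{loops[3] == ""}.
#' @slot lowConfidence logical; \code{TRUE} when any loop contains the
#'   ambiguity residue X.
#' @exportClass MotifMatch
setClass("MotifMatch", representation(
  sourceId = "character",
  cysPositions = "integer",
  loops = "character",
  lowConfidence = "logical"
))

setValidity("MotifMatch", function(object) {
  p <- object@cysPositions
  if (length(p) != 8L) return("cysPositions must have length 8")
  if (any(diff(p) <= 0L)) return("cysPositions must be strictly increasing")
  if (length(object@loops) != 7L) return("loops must have length 7")
  if (nchar(object@loops[3L]) != 0L)
    return("loop between Cys III and IV must be empty (tandem CC)")
  if (any(nchar(object@loops) != diff(p) - 1L))
    return("loop lengths inconsistent with cysteine positions")
  if (any(grepl("C", object@loops, fixed = TRUE)))
    return("loops must be cysteine-free")
  TRUE
})

#' Subfamily classification of an eight-cysteine framework
#'
#' @slot label one of \code{"ginsentide_like"},
#'   \code{"chitin_binding_8C_HLP"}, \code{"other_8C"}.
#' @slot evidence character vector of rule names that fired (empty only for
#'   \code{other_8C}).
#' @exportClass CRPClass
setClass("CRPClass", representation(
  label = "character",
  evidence = "character"
))

setValidity("CRPClass", function(object) {
  ok <- c("ginsentide_like", "chitin_binding_8C_HLP", "other_8C")
  if (length(object@label) != 1L || !object@label %in% ok)
    return("label must be exactly one of the three subfamily labels")
  if (object@label != "other_8C" && length(object@evidence) == 0L)
    return("evidence must be non-empty unless label is other_8C")
  TRUE
})

#' Three-domain CRP precursor model
#'
#' Models the signal peptide / prodomain / mature peptide architecture of
#' ginsentide-like precursors, with the asparaginyl-endopeptidase (AEP)
#' cleavage site between the prodomain's C-terminal Asn and the mature
#' domain's Cys I. All coordinates are 1-based residue indices in
#' \code{fullSeq}.
#'
#' @slot sourceId identifier of the precursor sequence.
#' @slot fullSeq full precursor protein sequence.
#' @slot signalEnd last residue of the signal peptide, or \code{NA} when
#'   neither supplied nor inferable.
#' @slot signalProvenance one of \code{"supplied"}, \code{"heuristic"},
#'   \code{"none"}.
#' @slot aepSite position of the Asn immediately preceding the mature domain.
#' @slot matureSeq mature peptide sequence (from \code{aepSite + 1} to the
#'   precursor C-terminus by default).
#' @exportClass PrecursorModel
setClass("PrecursorModel", representation(
  sourceId = "character",
  fullSeq = "character",
  signalEnd = "integer",
  signalProvenance = "character",
  aepSite = "integer",
  matureSeq = "character"
))

setValidity("PrecursorModel", function(object) {
  s <- object@fullSeq
  a <- object@aepSite
  if (substring(s, a, a) != "N") return("residue at aepSite must be Asn")
  if (substring(s, a + 1L, a + 1L) != "C")
    return("residue at matureStart must be Cys")
  if (!object@signalProvenance %in% c("supplied", "heuristic", "none"))
    return("invalid signalProvenance")
  if (!is.na(object@signalEnd) && object@signalEnd >= a)
    return("signalEnd must precede aepSite")
  TRUE
})

#' MS1 peak list
#'
#' A centroided MS1 peak list (m/z, intensity), kept sorted by ascending m/z.
#'
#' @slot peaks data.frame with numeric columns \code{mz} and
#'   \code{intensity}.
#' @slot source free-text provenance of the list.
#' @exportClass PeakList
setClass("PeakList", representation(
  peaks = "data.frame",
  source = "character"
))

setValidity("PeakList", function(object) {
  pk <- object@peaks
  if (!all(c("mz", "intensity") %in% names(pk)))
    return("peaks must have columns mz and intensity")
  if (nrow(pk)) {
    if (is.unsorted(pk$mz)) return("peaks must be sorted by ascending m/z")
    if (any(pk$intensity < 0)) return("intensities must be non-negative")
  }
  TRUE
})

setMethod("show", "MotifMatch", function(object) {
  cat("MotifMatch in '", object@sourceId, "'\n", sep = "")
  cat("  Cys I-VIII at:", paste(object@cysPositions, collapse = ", "), "\n")
  cat("  loop lengths :", paste(nchar(object@loops), collapse = ","), "\n")
  if (object@lowConfidence) cat("  [low confidence: X in a loop]\n")
})

setMethod("show", "CRPClass", function(object) {
  cat("CRPClass:", object@label, "\n")
  if (length(object@evidence))
    cat("  evidence:", paste(object@evidence, collapse = "; "), "\n")
})

setMethod("show", "PrecursorModel", function(object) {
  cat("PrecursorModel '", object@sourceId, "' (", nchar(object@fullSeq),
      " aa)\n", sep = "")
  cat("  signal end :", object@signalEnd,
      paste0("(", object@signalProvenance, ")"), "\n")
  cat("  AEP site   : Asn", object@aepSite, " | Cys", object@aepSite + 1L,
      "\n", sep = "")
  cat("  mature     :", object@matureSeq, "\n")
})

setMethod("show", "PeakList", function(object) {
  cat("PeakList (", nrow(object@peaks), " peaks) from ", object@source,
      "\n", sep = "")
  if (nrow(object@peaks))
    cat("  m/z range: ", min(object@peaks$mz), "-", max(object@peaks$mz),
        "\n", sep = "")
})

## ---- accessors -----------------------------------------------------------

#' @describeIn MotifMatch-accessors 1-based positions of Cys I-VIII
#' @export
cysPositions <- function(x) x@cysPositions

#' Accessors for MotifMatch objects
#'
#' @param x a \linkS4class{MotifMatch}.
#' @name MotifMatch-accessors
#' @return \code{cysPositions}: integer(8); \code{loopSeqs}: character(7) of
#'   inter-cysteine segments; \code{loopLengths}: integer(7);
#'   \code{motifSpan}: integer(2), first and last framework Cys position.
NULL

#' @describeIn MotifMatch-accessors inter-cysteine loop segments
#' @export
loopSeqs <- function(x) x@loops

#' @describeIn MotifMatch-accessors inter-cysteine loop lengths
#' @export
loopLengths <- function(x) nchar(x@loops)

#' @describeIn MotifMatch-accessors first..last framework Cys coordinates
#' @export
motifSpan <- function(x) range(x@cysPositions)

#' Accessors for PrecursorModel objects
#'
#' @param x a \linkS4class{PrecursorModel}.
#' @return \code{matureSeq}: the mature peptide string; \code{matureStart}:
#'   its 1-based start (Cys I = aepSite + 1); \code{aepSite}: the Asn
#'   position; \code{signalEnd}: last signal-peptide residue or NA.
#' @name PrecursorModel-accessors
NULL

#' @describeIn PrecursorModel-accessors mature peptide sequence
#' @export
matureSeq <- function(x) x@matureSeq

#' @describeIn PrecursorModel-accessors 1-based start of the mature domain
#' @export
matureStart <- function(x) x@aepSite + 1L

#' @describeIn PrecursorModel-accessors Asn position of the AEP site
#' @export
aepSite <- function(x) x@aepSite

#' @describeIn PrecursorModel-accessors last signal-peptide residue (or NA)
#' @export
signalEnd <- function(x) x@signalEnd

#' Accessors for PeakList objects
#'
#' @param x a \linkS4class{PeakList}.
#' @return \code{peaks}: data.frame of (mz, intensity);
#'   \code{peakCount}: number of peaks.
#' @name PeakList-accessors
NULL

#' @describeIn PeakList-accessors peak table
#' @export
peaks <- function(x) x@peaks

#' @describeIn PeakList-accessors number of peaks
#' @export
peakCount <- function(x) nrow(x@peaks)

#' @describeIn CRPClass-accessors subfamily label
#' @export
crpLabel <- function(x) x@label

#' Accessors for CRPClass objects
#'
#' @param x a \linkS4class{CRPClass}.
#' @return \code{crpLabel}: the subfamily label string;
#'   \code{classEvidence}: the classification rules that fired.
#' @name CRPClass-accessors
NULL

#' @describeIn CRPClass-accessors classification rules that fired
#' @export
classEvidence <- function(x) x@evidence
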