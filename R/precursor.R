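#' Find asparaginyl-endopeptidase (AEP) cleavage sites
#'
#' AEPs cleave C-terminally of Asn (and, more weakly, Asp). Ginsentide-like
#' precursors are matured at an Asn-Cys junction, releasing the mature
#' peptide whose first residue is Cys I of the eight-cysteine framework.
#' This reports every position p with \code{seq[p]} in \code{donors} and
#' \code{seq[p+1]} in \code{acceptors}.
#'
#' @param x a protein sequence.
#' @param donors residues cleaved after; default \code{"N"} (option
#'   \code{c("N","D")} for relaxed AEP specificity).
#' @param acceptors allowed residues immediately downstream; default
#'   \code{"C"}.
#' @return ascending integer vector of 1-based donor (Asn) positions.
#' @export
#' @examples
#' findAepSites("AANCGG")  # 3
#' findAepSites("NCNC")    # 1 3
findAepSites <- function(x, donors = "N", acceptors = "C") {
  seq <- .asSeqChar(x)
  if (!nchar(seq)) stop("sequence must be non-empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer())
  which(chars[-n] %in% donors & chars[-1L] %in% acceptors)
}

## Signal-peptide fallback: longest window of >= minWin residues within the
## first 40 whose mean Kyte-Doolittle hydropathy exceeds the cutoff;
## cleavage is placed 5 residues after the window's end. Returns NA when no
## window qualifies. A crude stand-in for a dedicated signal-peptide
## predictor; callers flag its output as approximate.
.signalEndHeuristic <- function(seq, minWin = 8L, cutoff = 1.5,
                                searchLen = 40L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- min(length(chars), searchLen)
  kd <- .KYTE_DOOLITTLE[chars[seq_len(n)]]
  kd[is.na(kd)] <- 0  # X and other ambiguity: neutral
  best <- NULL
  for (len in n:minWin) {
    for (s in 1:(n - len + 1L)) {
      if (mean(kd[s:(s + len - 1L)]) > cutoff) { best <- c(s, s + len - 1L); break }
    }
    if (!is.null(best)) break  # longest window wins; leftmost on ties
  }
  if (is.null(best)) return(NA_integer_)
  as.integer(best[2L] + 5L)
}

#' Parse a three-domain ginsentide-like precursor
#'
#' Models the signal peptide / prodomain / mature peptide architecture.
#' Among the Asn-Cys AEP sites of the sequence, the leftmost one whose
#' downstream segment begins with Cys I of a ginsentide-like
#' eight-cysteine framework is selected; the mature peptide runs from
#' that Cys to the precursor's C-terminus. When several sites qualify the
#' leftmost is chosen and the alternatives are reported in a message.
#'
#' The signal-peptide end is taken from \code{signalEnd} when supplied
#' (e.g. from an external predictor); otherwise a Kyte-Doolittle
#' hydrophobic-core heuristic is applied and the result flagged
#' \code{"heuristic"} (or \code{"none"} when no hydrophobic core is found).
#'
#' @param x the precursor protein sequence.
#' @param signalEnd optional 1-based position of the last signal-peptide
#'   residue.
#' @param bounds loop bounds passed to \code{\link{scanCrpMotif}}.
#' @param sourceId identifier; defaults to the sequence's name.
#' @return a \linkS4class{PrecursorModel}.
#' @export
parsePrecursor <- function(x, signalEnd = NULL, bounds = crpLoopBounds(),
                           sourceId = NULL) {
  if (is.null(sourceId)) sourceId <- .seqId(x)
  seq <- .asSeqChar(x)
  sites <- findAepSites(seq)
  chosen <- NA_integer_
  qualifying <- integer()
  for (p in sites) {
    downstream <- substring(seq, p + 1L)
    mm <- scanCrpMotif(downstream, bounds = bounds, sourceId = sourceId)
    if (length(mm) && mm[[1L]]@cysPositions[1L] == 1L &&
        crpLabel(classify8cHlp(mm[[1L]])) == "ginsentide_like")
      qualifying <- c(qualifying, p)
  }
  if (!length(qualifying))
    stop("no mature domain: no Asn-Cys site is followed by a ",
         "ginsentide-like eight-cysteine framework in '", sourceId, "'")
  chosen <- qualifying[1L]
  if (length(qualifying) > 1L)
    message("precursor '", sourceId, "': ", length(qualifying),
            " qualifying AEP sites; using leftmost (alternatives at ",
            paste(qualifying[-1L], collapse = ", "), ")")
  if (!is.null(signalEnd)) {
    signalEnd <- as.integer(signalEnd)
    prov <- "supplied"
    if (signalEnd >= chosen)
      stop("inconsistent domains: signalEnd (", signalEnd,
           ") must precede the AEP site (", chosen, ")")
  } else {
    signalEnd <- .signalEndHeuristic(seq)
    prov <- if (is.na(signalEnd)) "none" else "heuristic"
    if (!is.na(signalEnd) && signalEnd >= chosen) {
      signalEnd <- NA_integer_
      prov <- "none"
    }
  }
  methods::new("PrecursorModel", sourceId = sourceId, fullSeq = seq,
               signalEnd = signalEnd, signalProvenance = prov,
               aepSite = chosen, matureSeq = substring(seq, chosen + 1L))
}

#' Excise the mature peptide from a precursor model
#'
#' @param model a \linkS4class{PrecursorModel}.
#' @return a length-1 \code{AAStringSet} named
#'   \code{"<sourceId>|mature"} whose header description carries the
#'   1-based inclusive coordinates of the mature domain in the precursor.
#' @export
exciseMature <- function(model) {
  stopifnot(methods::is(model, "PrecursorModel"))
  s <- model@matureSeq
  out <- Biostrings::AAStringSet(s)
  names(out) <- sprintf("%s|mature residues %d-%d of %d",
                        model@sourceId, matureStart(model),
                        nchar(model@fullSeq), nchar(model@fullSeq))
  out
}
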