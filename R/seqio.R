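#' Read sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a Biostrings container
#' (\code{DNAStringSet} or \code{AAStringSet}), validating every record
#' against the declared alphabet: \code{ACGTN} for nucleotides, the 20
#' canonical amino acids plus \code{X} for proteins. Sequences are
#' uppercased; record order is preserved. Names hold the full header line
#' (identifier plus description).
#'
#' Duplicate identifiers (the header token before the first whitespace) are
#' tolerated but flagged with a warning, as are empty files.
#'
#' @param path path to a FASTA file.
#' @param kind \code{"protein"} or \code{"nucleotide"}.
#' @return an \code{AAStringSet} (protein) or \code{DNAStringSet}
#'   (nucleotide).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT"), fa)
#' readFasta(fa, kind = "nucleotide")
readFasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## Read as BStringSet first so alphabet violations give our error, not
  ## Biostrings' parser error.
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(if (kind == "protein") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet())
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(nchar(seqs) == 0L))
    stop("record '", ids[which(nchar(seqs) == 0L)[1L]], "': empty sequence")
  for (i in seq_along(seqs)) {
    if (kind == "protein") {
      .checkProteinAlphabet(seqs[i], ids[i])
    } else {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
      if (length(bad))
        stop(sprintf("record '%s': illegal nucleotide '%s' at position %d",
                     ids[i], chars[bad[1L]], bad[1L]))
    }
  }
  if (anyDuplicated(ids))
    warning("duplicate sequence id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- if (kind == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Write sequences to a FASTA file
#'
#' Writes an \code{XStringSet} (or named character vector) as FASTA, wrapped
#' at 60 columns.
#'
#' @param x sequences (\code{XStringSet} or named character vector).
#' @param path output path.
#' @param width line-wrap width in columns.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates one nucleotide sequence in all six reading frames with the
#' standard genetic code. Frames \code{+1,+2,+3} start at offsets 0,1,2 on
#' the forward strand; \code{-1,-2,-3} at offsets 0,1,2 on the reverse
#' complement. Stop codons become \code{*}; codons containing \code{N}
#' translate to \code{X}. Sequences shorter than one codon yield six empty
#' frames.
#'
#' @param x a single nucleotide sequence (\code{DNAString}, length-1
#'   \code{DNAStringSet}, or character scalar over ACGTN).
#' @param sourceId identifier used in frame names; defaults to the
#'   sequence's name or \code{"seq"}.
#' @return an \code{AAStringSet} of 6 frames; \code{mcols} carries
#'   \code{sourceId}, \code{frame} (+1..+3, -1..-3) and \code{offset}
#'   (0-based offset of the frame start on its own strand).
#' @export
#' @examples
#' sixFrameTranslate("ATG")   # frame +1 is "M"
sixFrameTranslate <- function(x, sourceId = NULL) {
  if (is.null(sourceId)) sourceId <- .seqId(x)
  s <- .asSeqChar(x)
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  translateFrame <- function(dna, off) {
    n <- length(dna) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    codons <- Biostrings::subseq(dna, off + 1L, off + n)
    as.character(Biostrings::translate(codons, if.fuzzy.codon = "X"))
  }
  seqs <- c(vapply(0:2, function(o) translateFrame(fwd, o), character(1)),
            vapply(0:2, function(o) translateFrame(rev, o), character(1)))
  out <- Biostrings::AAStringSet(seqs)
  frame <- c(1L, 2L, 3L, -1L, -2L, -3L)
  names(out) <- paste0(sourceId, "|frame", ifelse(frame > 0, "+", ""), frame)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    sourceId = sourceId, frame = frame, offset = rep(0:2, 2))
  out
}

#' Find open reading frames in translated frames
#'
#' Scans translated frames for maximal Met-initiated, stop-terminated
#' segments of at least \code{minLen} residues (stop excluded). Within each
#' stop-delimited stretch the ORF runs from the first Met to the stop.
#'
#' @param frames an \code{AAStringSet} as produced by
#'   \code{\link{sixFrameTranslate}} (\code{mcols} with sourceId/frame), or
#'   any \code{AAStringSet} of frame translations containing \code{*}.
#' @param minLen minimum ORF length in residues (>= 1), stop excluded.
#' @param requireMet require an initiator Met (default); when \code{FALSE}
#'   each stop-delimited stretch is reported whole.
#' @param requireStop drop trailing segments lacking a stop codon (default
#'   \code{TRUE}).
#' @return an \code{AAStringSet} of ORFs. Names are
#'   \code{"<sourceId>|frame<f>|<start>-<end>"} with 1-based inclusive
#'   residue coordinates in the frame translation; \code{mcols} carries
#'   sourceId, frame, start, end.
#' @export
findOrfs <- function(frames, minLen = 1L, requireMet = TRUE,
                     requireStop = TRUE) {
  stopifnot(minLen >= 1L)
  mc <- S4Vectors::mcols(frames)
  hasMeta <- !is.null(mc) && all(c("sourceId", "frame") %in% names(mc))
  out <- list()
  for (i in seq_along(frames)) {
    fseq <- as.character(frames[[i]])
    sid <- if (hasMeta) mc$sourceId[i] else .seqId(frames[i], "frame")
    frm <- if (hasMeta) mc$frame[i] else NA_integer_
    if (!nchar(fseq)) next
    ## stop-delimited stretches with their coordinates
    stops <- c(gregexpr("\\*", fseq)[[1L]])
    stops <- stops[stops > 0]
    bounds <- c(0L, stops, if (requireStop) integer() else nchar(fseq) + 1L)
    segStart <- head(bounds, -1L) + 1L
    segEnd <- tail(bounds, -1L) - 1L
    for (k in seq_along(segStart)) {
      if (segEnd[k] < segStart[k]) next
      seg <- substring(fseq, segStart[k], segEnd[k])
      if (requireMet) {
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0) next
        s <- segStart[k] + as.integer(m) - 1L
      } else s <- segStart[k]
      e <- segEnd[k]
      if (e - s + 1L < minLen) next
      orf <- substring(fseq, s, e)
      nm <- sprintf("%s|frame%s%s|%d-%d", sid,
                    ifelse(!is.na(frm) && frm > 0, "+", ""),
                    ifelse(is.na(frm), "?", frm), s, e)
      out[[length(out) + 1L]] <- list(seq = orf, name = nm, sid = sid,
                                      frame = frm, start = s, end = e)
    }
  }
  if (!length(out)) {
    res <- Biostrings::AAStringSet()
    S4Vectors::mcols(res) <- S4Vectors::DataFrame(
      sourceId = character(), frame = integer(),
      start = integer(), end = integer())
    return(res)
  }
  res <- Biostrings::AAStringSet(vapply(out, `[[`, character(1), "seq"))
  names(res) <- vapply(out, `[[`, character(1), "name")
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    sourceId = vapply(out, `[[`, character(1), "sid"),
    frame = vapply(out, function(z) as.integer(z$frame), integer(1)),
    start = vapply(out, function(z) as.integer(z$start), integer(1)),
    end = vapply(out, function(z) as.integer(z$end), integer(1)))
  res
}
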