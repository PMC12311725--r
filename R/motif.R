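#' Loop-length bounds for the eight-cysteine framework
#'
#' The framework CXnCXnCCXnCXCXnCXnC leaves the seven inter-cysteine loop
#' lengths unconstrained; these defaults bracket the ginsentide/cocotide
#' scale without admitting arbitrary cysteine ladders. Loop 3 is the tandem
#' CC and is fixed at length 0. Loops are numbered between consecutive
#' framework cysteines (loop k separates Cys k and Cys k+1); note the
#' hevein-literature convention skips the empty CC gap, so its "loop 3"
#' (Cys IV-V) is loop 4 here and its "loop 4" (Cys V-VI) is loop 5 here.
#'
#' @param min integer(7) of per-loop minima.
#' @param max integer(7) of per-loop maxima.
#' @return a 7 x 2 integer matrix with columns \code{min}, \code{max}.
#' @export
#' @examples
#' crpLoopBounds()
crpLoopBounds <- function(min = c(2L, 2L, 0L, 1L, 1L, 2L, 1L),
                          max = c(12L, 12L, 0L, 8L, 8L, 12L, 10L)) {
  min <- as.integer(min); max <- as.integer(max)
  stopifnot(length(min) == 7L, length(max) == 7L, all(min <= max),
            min[3L] == 0L, max[3L] == 0L, all(min >= 0L))
  cbind(min = min, max = max)
}

#' Scan a protein sequence for eight-cysteine CRP frameworks
#'
#' Locates occurrences of the eight-cysteine framework
#' CXnCXnCCXnCXCXnCXnC: eight cysteines whose seven intervening loops are
#' cysteine-free and satisfy per-loop length bounds, with the third loop
#' empty (the tandem CC). Because loops must be cysteine-free, a framework
#' always consists of eight consecutive cysteines of the sequence;
#' overlapping candidates are resolved greedily left to right so that no
#' two reported matches share a cysteine. Matches whose loops contain the
#' ambiguity residue X are flagged low-confidence.
#'
#' @param x a protein sequence (character scalar, \code{AAString}, or
#'   length-1 \code{AAStringSet}).
#' @param bounds loop-length bounds from \code{\link{crpLoopBounds}}.
#' @param sourceId identifier recorded in matches; defaults to the
#'   sequence's name.
#' @return a list of \linkS4class{MotifMatch}, left to right (possibly
#'   empty).
#' @export
#' @examples
#' tc1 <- "CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC"
#' m <- scanCrpMotif(tc1)[[1]]
#' cysPositions(m)
#' loopLengths(m)   # 6 6 0 2 1 6 4
scanCrpMotif <- function(x, bounds = crpLoopBounds(), sourceId = NULL) {
  if (is.null(sourceId)) sourceId <- .seqId(x)
  seq <- .asSeqChar(x)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cys <- which(chars == "C")
  matches <- list()
  i <- 1L
  while (i + 7L <= length(cys)) {
    pos <- cys[i:(i + 7L)]
    gaps <- diff(pos) - 1L
    if (all(gaps >= bounds[, "min"]) && all(gaps <= bounds[, "max"])) {
      loops <- vapply(1:7, function(k)
        substring(seq, pos[k] + 1L, pos[k + 1L] - 1L), character(1))
      matches[[length(matches) + 1L]] <- methods::new(
        "MotifMatch", sourceId = sourceId, cysPositions = pos,
        loops = loops,
        lowConfidence = any(grepl("X", loops, fixed = TRUE)))
      i <- i + 8L  # greedy: framework cysteines are consumed
    } else {
      i <- i + 1L
    }
  }
  matches
}

#' Classify an eight-cysteine framework match
#'
#' Applies the two subfamily rules for eight-cysteine hevein-like peptides:
#' \itemize{
#'   \item \emph{ginsentide-like}: the Cys V-VI loop is a single residue
#'     (the shortened CXC motif), and the chitin-binding domain is absent;
#'   \item \emph{chitin-binding 8C-HLP}: the Cys IV-V loop contains the
#'     conserved S-x-Phi-x-Phi chitin-binding domain (Phi aromatic, one of
#'     F/Y/W) \emph{and} the Cys V-VI loop has exactly six residues with at
#'     least one aromatic.
#' }
#' Frameworks satisfying neither rule are labelled \code{other_8C}.
#'
#' @param match a \linkS4class{MotifMatch}.
#' @return a \linkS4class{CRPClass}.
#' @export
classify8cHlp <- function(match) {
  stopifnot(methods::is(match, "MotifMatch"))
  loop45 <- match@loops[4L]  # Cys IV-V ("loop 3" in hevein numbering)
  loop56 <- match@loops[5L]  # Cys V-VI ("loop 4" in hevein numbering)
  evidence <- character()
  if (nchar(loop56) == 1L) {
    evidence <- "cysV_VI_loop_length_1_CXC"
    label <- "ginsentide_like"
  } else {
    hasSxPxP <- grepl("S.[FYW].[FYW]", loop45)
    sixAromatic <- nchar(loop56) == 6L && grepl("[FYW]", loop56)
    if (hasSxPxP && sixAromatic) {
      evidence <- c("cysIV_V_SxPhixPhi_domain",
                    "cysV_VI_loop_length_6_aromatic")
      label <- "chitin_binding_8C_HLP"
    } else {
      label <- "other_8C"
    }
  }
  methods::new("CRPClass", label = label, evidence = evidence)
}

#' Assign the fixed ginsentide disulfide connectivity
#'
#' Maps the conserved pairing Cys I-IV, II-VI, III-VII, V-VIII onto the
#' cysteine positions of a framework match. The four pairs form a perfect
#' matching on the eight cysteines and close the pseudocyclic fold.
#'
#' @param match a \linkS4class{MotifMatch}.
#' @return a data.frame with columns \code{romanPair}, \code{pos1},
#'   \code{pos2} (1-based residue indices).
#' @export
#' @examples
#' m <- scanCrpMotif("CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC")[[1]]
#' assignConnectivity(m)   # (1,16) (8,21) (15,28) (19,33)
assignConnectivity <- function(match) {
  stopifnot(methods::is(match, "MotifMatch"))
  idx <- rbind(c(1L, 4L), c(2L, 6L), c(3L, 7L), c(5L, 8L))
  data.frame(
    romanPair = c("I-IV", "II-VI", "III-VII", "V-VIII"),
    pos1 = match@cysPositions[idx[, 1L]],
    pos2 = match@cysPositions[idx[, 2L]],
    stringsAsFactors = FALSE)
}

#' Percent identity between two protein sequences
#'
#' For equal-length sequences: ungapped identity, 100 x matches / length.
#' For unequal lengths: identity over a Needleman-Wunsch global alignment
#' (match 1, mismatch 0, linear gap penalty 1, via
#' \code{Biostrings::pairwiseAlignment}), as 100 x matches / alignment
#' length. Symmetric in its arguments.
#'
#' @param a,b protein sequences (character or AAString).
#' @return percent identity (numeric scalar).
#' @export
#' @examples
#' pairwiseIdentity("MKV", "MKL")  # 66.67
pairwiseIdentity <- function(a, b) {
  a <- .asSeqChar(a); b <- .asSeqChar(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    return(100 * sum(ca == cb) / length(ca))
  }
  ## canonical argument order keeps the statistic symmetric under any
  ## traceback tie-breaking inside the aligner
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  alpha <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1L]])
  sub <- matrix(0, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Residue composition and net formal charge
#'
#' Counts each canonical residue, reports percentages rounded half-up to
#' one decimal, and the net formal charge at neutral pH counting Asp/Glu as
#' -1, Lys/Arg as +1, His as 0, and the free termini as +1/-1 (cancelling).
#'
#' @param x a protein sequence over the 20 canonical residues.
#' @return a list with \code{length}, \code{counts} (named integer over the
#'   20 residues), \code{percents} (named numeric, one decimal),
#'   \code{netFormalCharge} (integer).
#' @export
#' @examples
#' computeComposition("CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC")$counts[["C"]]  # 8
computeComposition <- function(x) {
  seq <- .asSeqChar(x)
  if (!nchar(seq)) stop("sequence must be non-empty")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA20)
  if (length(bad))
    stop("non-canonical residue(s) at position(s): ",
         paste(bad, collapse = ", "))
  counts <- setNames(integer(length(.AA20)), .AA20)
  tab <- table(chars)
  counts[names(tab)] <- as.integer(tab)
  percents <- .roundHalfUp(100 * counts / length(chars), 1L)
  charge <- sum(counts[c("K", "R")]) - sum(counts[c("D", "E")])
  list(length = length(chars), counts = counts, percents = percents,
       netFormalCharge = as.integer(charge))
}
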