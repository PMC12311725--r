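#' Build a two-group protein quantification container
#'
#' Wraps a proteins x samples intensity matrix and its control/treatment
#' design in a \code{SummarizedExperiment} (assay \code{"intensity"},
#' \code{colData$group}).
#'
#' @param values numeric matrix, proteins in rows, samples in columns;
#'   non-negative, \code{NA} for missing.
#' @param groups character/factor of \code{"control"}/\code{"treatment"}
#'   per sample.
#' @return a \code{SummarizedExperiment}.
#' @export
quantMatrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(groups, levels = c("control", "treatment"))
  if (anyNA(groups))
    stop("groups must be 'control' or 'treatment'")
  if (length(groups) != ncol(values))
    stop("one group label per sample column required")
  if (any(table(groups) < 2L))
    stop("need >= 2 samples per group")
  if (any(values < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values),
    colData = S4Vectors::DataFrame(group = groups))
}

#' Per-protein fold change and Welch significance
#'
#' For each protein: intensities get a pseudocount, are log2-transformed,
#' and compared between groups. Reported are \code{log2fc} (treatment mean
#' minus control mean on the log2 scale), the two-sided Welch t-test
#' p-value, and \code{significance = -10 log10(p)} -- the scale on which
#' the conventional enrichment cutoff of 15 corresponds to p ~ 0.032. The
#' Welch statistic here is a documented approximation of the proprietary
#' significance reported by common proteomics software.
#'
#' Degenerate rows with zero variance in both groups get p = 1 when the
#' means are equal (and p = 0 when not, flooring p at
#' \code{.Machine$double.xmin} so the significance stays finite). Proteins
#' with fewer than two finite values in either group are untestable: they
#' are excluded from the result and reported via
#' \code{attr(, "untestable")} and a message.
#'
#' @param se a \code{SummarizedExperiment} from \code{\link{quantMatrix}}.
#' @param pseudocount added to raw intensities before log2 (default 1).
#' @return a \code{data.frame} with columns \code{protein}, \code{log2fc},
#'   \code{pvalue}, \code{significance}; attribute \code{untestable} lists
#'   excluded protein ids.
#' @export
proteinStats <- function(se, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  x <- SummarizedExperiment::assay(se, "intensity")
  grp <- SummarizedExperiment::colData(se)$group
  lx <- log2(x + pseudocount)
  ctl <- lx[, grp == "control", drop = FALSE]
  trt <- lx[, grp == "treatment", drop = FALSE]
  nOkC <- rowSums(is.finite(ctl))
  nOkT <- rowSums(is.finite(trt))
  testable <- nOkC >= 2L & nOkT >= 2L
  if (any(!testable))
    message(sum(!testable), " protein(s) untestable ",
            "(<2 finite values in a group); excluded")
  stats <- lapply(which(testable), function(i) {
    a <- ctl[i, ]; a <- a[is.finite(a)]
    b <- trt[i, ]; b <- b[is.finite(b)]
    fc <- mean(b) - mean(a)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else
        .Machine$double.xmin
    } else {
      p <- stats::t.test(b, a, var.equal = FALSE)$p.value
    }
    c(fc, p)
  })
  m <- do.call(rbind, stats)
  out <- data.frame(
    protein = rownames(x)[testable],
    log2fc = if (length(stats)) m[, 1L] else numeric(),
    pvalue = if (length(stats)) m[, 2L] else numeric(),
    stringsAsFactors = FALSE)
  out$significance <- -10 * log10(out$pvalue)
  attr(out, "untestable") <- rownames(x)[!testable]
  rownames(out) <- NULL
  out
}

#' Volcano-style enrichment filter
#'
#' The enrichment rule used for affinity-capture and TMT comparisons:
#' enriched proteins change by at least \code{minFc}-fold upward
#' (\code{log2fc >= log2(minFc)}) with \code{significance > minSig};
#' depleted proteins are the mirror image. The two sets are disjoint by
#' construction. No multiple-testing correction is applied by default
#' (\code{adjust = "BH"} switches the significance to Benjamini-Hochberg
#' adjusted p-values).
#'
#' @param stats result of \code{\link{proteinStats}}.
#' @param minFc minimum fold change (>= 1), on the raw scale (2 = 2-fold).
#' @param minSig minimum significance, exclusive.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return a list with character vectors \code{enriched} and
#'   \code{depleted}, plus the annotated \code{stats} table (added
#'   \code{direction} column: up/down/ns).
#' @export
volcanoFilter <- function(stats, minFc = 2, minSig = 15,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(minFc >= 1)
  sig <- stats$significance
  if (adjust == "BH")
    sig <- -10 * log10(stats::p.adjust(stats$pvalue, "BH"))
  lfc <- log2(minFc)
  up <- stats$log2fc >= lfc & sig > minSig
  down <- stats$log2fc <= -lfc & sig > minSig
  stats$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(enriched = stats$protein[up], depleted = stats$protein[down],
       stats = stats)
}

#' Exclude contaminant proteins from a hit list
#'
#' Set difference against a contaminant catalogue (e.g. common
#' affinity-purification background proteins), reporting what was removed.
#'
#' @param ids character vector of protein ids.
#' @param contaminants character vector of contaminant ids.
#' @return list with \code{kept} and \code{removed} character vectors.
#' @export
#' @examples
#' excludeContaminants(c("A", "B", "C"), "B")
excludeContaminants <- function(ids, contaminants) {
  removed <- intersect(ids, contaminants)
  list(kept = setdiff(ids, contaminants), removed = removed)
}

#' Read a contaminant list (one identifier per line)
#'
#' @param path text file, one id per line; blank and \code{#} lines
#'   skipped.
#' @return character vector of ids.
#' @export
readContaminants <- function(path) {
  if (!file.exists(path)) stop("contaminant list not found: ", path)
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
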