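## Internal helpers shared across modules.

## Round half away from zero at `digits` decimals (base round() is banker's).
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Coerce the various sequence containers to a plain uppercase character
## scalar, keeping a usable identifier for error messages.
.asSeqChar <- function(x) {
  if (methods::is(x, "XString")) x <- as.character(x)
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got ", length(x))
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single string or an XString(Set) of length 1")
  unname(toupper(x))
}

.seqId <- function(x, default = "seq") {
  nm <- NULL
  if (methods::is(x, "XStringSet")) nm <- names(x)
  if (is.character(x)) nm <- names(x)
  if (is.null(nm) || !nzchar(nm[1L])) default else sub("\\s.*$", "", nm[1L])
}

## Validate a protein string against the canonical alphabet (+X optionally).
.checkProteinAlphabet <- function(seq, id = "seq", allowX = TRUE,
                                  allowStop = FALSE) {
  allowed <- .AA20
  if (allowX) allowed <- c(allowed, "X")
  if (allowStop) allowed <- c(allowed, "*")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, chars[bad[1L]], bad[1L]))
  invisible(TRUE)
}

## Polynomial rolling hash of a string; used to stamp output files with a
## config fingerprint without any external dependency. Not cryptographic.
.configHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

## TSV writer that prepends '# ' comment headers (config hash, seed, notes).
.writeTsv <- function(df, path, headerLines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in headerLines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
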