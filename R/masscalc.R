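#' Peptide mass with disulfide correction
#'
#' Sums residue masses plus one water, subtracting the mass of two hydrogen
#' atoms (2.01565 Da monoisotopic) per disulfide bond. The eight-cysteine
#' ginsentide framework carries four disulfides in its native form.
#'
#' @param x protein sequence over the 20 canonical residues.
#' @param nDisulfides number of disulfide bonds (default 0 = fully
#'   reduced); must not exceed \code{floor(nCys / 2)}.
#' @param scale \code{"monoisotopic"} (default) or \code{"average"}.
#' @return mass in Da.
#' @export
#' @examples
#' peptideMass("GG")                       # 132.0535
#' peptideMass("CLSAGGFCMFNPMDCCGNCGCLYPMGICYGSGC", nDisulfides = 4)
peptideMass <- function(x, nDisulfides = 0L,
                        scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  seq <- .asSeqChar(x)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA20)
  if (length(bad))
    stop("unknown residue '", chars[bad[1L]], "' at position ", bad[1L])
  nCys <- sum(chars == "C")
  nDisulfides <- as.integer(nDisulfides)
  if (nDisulfides < 0L || nDisulfides > nCys %/% 2L)
    stop("nDisulfides (", nDisulfides, ") exceeds capacity of ", nCys,
         " cysteine(s)")
  tab <- if (scale == "monoisotopic") .MONO_RESIDUE else .AVG_RESIDUE
  water <- if (scale == "monoisotopic") .WATER_MONO else .WATER_AVG
  twoH <- if (scale == "monoisotopic") .TWO_H_MONO else .TWO_H_AVG
  sum(tab[chars]) + water - nDisulfides * twoH
}

#' Total mass shift of a set of modifications
#'
#' Sums \code{count x per-unit shift} over modification specs. Known
#' modifications and their monoisotopic per-unit shifts:
#' carbamidomethyl +57.02146 Da (iodoacetamide on Cys), met_oxidation
#' +15.99491 Da (Met to Met(O), nominal 16 Da), disulfide_reduction
#' +2.01565 Da per bond (2 H regained).
#'
#' @param mods named numeric vector of counts, e.g.
#'   \code{c(carbamidomethyl = 8)}, or a data.frame with columns
#'   \code{name}, \code{count}.
#' @param scale \code{"monoisotopic"} or \code{"average"}.
#' @return shift in Da (0 for an empty spec).
#' @export
#' @examples
#' modificationShift(c(met_oxidation = 1))     # +15.9949
#' modificationShift(c(carbamidomethyl = 8))   # +456.1717
modificationShift <- function(mods, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  if (is.data.frame(mods)) mods <- setNames(mods$count, mods$name)
  if (!length(mods)) return(0)
  nm <- names(mods)
  unknown <- setdiff(nm, names(.MOD_SHIFTS))
  if (length(unknown))
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  if (any(mods < 0)) stop("modification counts must be >= 0")
  sum(vapply(seq_along(mods),
             function(i) mods[[i]] * .MOD_SHIFTS[[nm[i]]][[scale]],
             numeric(1)))
}

#' Mass shift from S-reduction and S-carbamidomethylation
#'
#' The shift from the native disulfide-bonded peptide to its fully reduced,
#' iodoacetamide-alkylated derivative: +57.02146 Da per cysteine plus
#' +2.01565 Da per reduced disulfide bond. For the eight-cysteine,
#' four-disulfide framework this is 464.23 Da (nominal 464), the shift used
#' to count cysteines from a MALDI mass difference.
#'
#' @param nCys number of cysteines.
#' @param nDisulfides number of disulfide bonds in the native form.
#' @return shift in Da.
#' @export
#' @examples
#' nominalDa(reductionAlkylationShift(8, 4))  # 464
reductionAlkylationShift <- function(nCys, nDisulfides) {
  nCys <- as.integer(nCys); nDisulfides <- as.integer(nDisulfides)
  if (nCys < 0L || nDisulfides < 0L || nCys < 2L * nDisulfides)
    stop("need nCys >= 2 * nDisulfides (got ", nCys, ", ", nDisulfides, ")")
  nCys * .MOD_SHIFTS$carbamidomethyl[["monoisotopic"]] +
    nDisulfides * .TWO_H_MONO
}

#' Infer the cysteine count from an observed alkylation shift
#'
#' Inverts \code{\link{reductionAlkylationShift}}: finds the cysteine count
#' n whose predicted shift (assuming \code{floor(n/2)} disulfides when
#' \code{assumeMaxSS}) is nearest the observed shift, requiring the
#' residual to be within \code{tol}; ties go to the smaller n.
#'
#' @param observedShift observed mass increase in Da (>= 0).
#' @param assumeMaxSS assume the native peptide was maximally
#'   disulfide-bonded (default TRUE).
#' @param tol maximum acceptable residual in Da.
#' @param maxN largest cysteine count considered.
#' @return integer cysteine count.
#' @export
#' @examples
#' inferCysCount(464, tol = 2)  # 8
inferCysCount <- function(observedShift, assumeMaxSS = TRUE, tol = 2,
                          maxN = 60L) {
  stopifnot(observedShift >= 0, tol > 0)
  n <- 0:maxN
  ss <- if (assumeMaxSS) n %/% 2L else 0L
  pred <- n * .MOD_SHIFTS$carbamidomethyl[["monoisotopic"]] +
    ss * .TWO_H_MONO
  resid <- abs(observedShift - pred)
  ord <- order(resid, n)  # ties toward smaller n
  if (resid[ord[1L]] > tol)
    stop(sprintf(
      "ambiguous shift %.3f Da: nearest candidates n=%d (resid %.3f) and n=%d (resid %.3f) exceed tol %.3f",
      observedShift, n[ord[1L]], resid[ord[1L]], n[ord[2L]],
      resid[ord[2L]], tol))
  n[ord[1L]]
}

#' m/z of a protonated ion
#'
#' \code{(mass + charge x 1.007276) / charge}; MALDI spectra of peptides in
#' this size range are dominated by the singly protonated [M+H]+ species.
#'
#' @param mass neutral mass in Da.
#' @param charge positive integer charge state.
#' @return m/z.
#' @export
#' @examples
#' massToMz(3368.128, 1)  # 3369.135
massToMz <- function(mass, charge = 1L) {
  charge <- as.integer(charge)
  stopifnot(charge >= 1L)
  (mass + charge * .PROTON) / charge
}
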