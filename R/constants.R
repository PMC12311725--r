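## Single source of truth for all mass constants used in the package.
## Residue masses are for the amino-acid *residue* (monomer minus water);
## a free peptide adds one water. Monoisotopic values to 1e-5 Da.

#' @keywords internal
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04048,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @keywords internal
.AVG_RESIDUE <- c(
  G = 57.0514, A = 71.0780, S = 87.0774, P = 97.1154, V = 99.1313,
  T = 101.1040, C = 103.1428, L = 113.1579, I = 113.1579, N = 114.1028,
  D = 115.0876, Q = 128.1294, K = 128.1725, E = 129.1142, M = 131.1960,
  H = 137.1395, F = 147.1742, R = 156.1859, Y = 163.1736, W = 186.2103
)

.WATER_MONO <- 18.010565
.WATER_AVG  <- 18.0153
.PROTON     <- 1.007276

## Mass of 2 H atoms: lost when a disulfide bond forms, regained on reduction.
.TWO_H_MONO <- 2.015650
.TWO_H_AVG  <- 2.0159

## Per-unit modification shifts (monoisotopic / average), positive = gain.
.MOD_SHIFTS <- list(
  carbamidomethyl     = c(monoisotopic = 57.02146, average = 57.0513),
  met_oxidation       = c(monoisotopic = 15.99491, average = 15.9994),
  disulfide_reduction = c(monoisotopic = .TWO_H_MONO, average = .TWO_H_AVG)
)

## Kyte-Doolittle hydropathy index, used only by the signal-peptide fallback.
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

.AA20 <- names(.MONO_RESIDUE)

#' Nominal mass rounding
#'
#' Rounds half away from zero to the nearest integer, the convention used
#' when reporting nominal Da shifts (e.g. the 464 Da alkylation shift or the
#' 16 Da methionine-sulfoxide shift).
#'
#' @param x numeric vector of masses in Da.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' nominalDa(464.23)   # 464
#' nominalDa(15.99491) # 16
nominalDa <- function(x) sign(x) * floor(abs(x) + 0.5)
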