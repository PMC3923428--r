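# Standard residue masses (Da) for the 20 amino acids: conventional
# average (chemical) and monoisotopic values, plus water and the proton.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

WATER_AVERAGE <- 18.0153
WATER_MONO <- 18.010565
PROTON_MASS <- 1.00728

#' Parse a peptide sequence
#'
#' Accepts one-letter codes; whitespace and hyphens (typographic line
#' breaks in printed sequences) are stripped. Any other character raises a
#' parse error naming its position.
#'
#' @param seq character scalar.
#' @return character vector of residues.
#' @export
parse_peptide <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  clean <- gsub("[-[:space:]]", "", seq)
  if (nchar(clean) == 0) stop_invalid("peptide sequence is empty")
  res <- strsplit(toupper(clean), "")[[1]]
  bad <- which(!res %in% names(AVERAGE_RESIDUE_MASS))
  if (length(bad)) {
    stop_invalid("invalid residue code '%s' at position %d",
                 res[bad[1]], bad[1])
  }
  res
}

#' Peptide masses and charge-state m/z
#'
#' `average_mass` sums conventional average residue masses plus one water
#' (18.0153 Da); `monoisotopic_mass` uses monoisotopic residue masses plus
#' water 18.010565 Da. `mz_for_charge` converts a neutral mass to the m/z
#' of the z-protonated ion, `(M + z * 1.00728) / z`.
#'
#' @param seq peptide sequence (one-letter codes; hyphens/whitespace
#'   ignored).
#' @return mass in Da (full precision; report to 2 decimals by convention).
#' @examples
#' average_mass("G")                      # 75.07 (glycine)
#' mz_for_charge(monoisotopic_mass("SGEGDFLAEGGGVR"), 2)  # ~675.82
#' @export
average_mass <- function(seq) {
  sum(AVERAGE_RESIDUE_MASS[parse_peptide(seq)]) + WATER_AVERAGE
}

#' @rdname average_mass
#' @export
monoisotopic_mass <- function(seq) {
  sum(MONOISOTOPIC_RESIDUE_MASS[parse_peptide(seq)]) + WATER_MONO
}

#' @rdname average_mass
#' @param neutral_mass neutral (uncharged) mass in Da.
#' @param z charge state, a positive integer.
#' @export
mz_for_charge <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z))) {
    stop_invalid("charge z must be a positive integer")
  }
  (neutral_mass + z * PROTON_MASS) / z
}

#' Check whether two peaks form a singly/doubly-charged pair
#'
#' A peak observed at `mz_single` and assumed singly charged predicts a
#' doubly-charged companion at `(mz_single + 1.00728) / 2`. Returns TRUE
#' when the observed `mz_double` lies within `tol` Da of that prediction —
#' the arithmetic behind attributing m/z 2903.3 to the 2+ form of the
#' m/z 5805.0 peptide.
#'
#' @param mz_single observed singly-charged peak m/z (`> mz_double`).
#' @param mz_double observed candidate doubly-charged peak m/z.
#' @param tol tolerance in Da (`> 0`).
#' @return logical.
#' @export
charge_pair_check <- function(mz_single, mz_double, tol = 0.5) {
  if (any(mz_single <= mz_double)) {
    stop_invalid("mz_single must exceed mz_double")
  }
  if (tol <= 0) stop_invalid("tol must be > 0")
  abs(mz_double - (mz_single + PROTON_MASS) / 2) <= tol
}
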