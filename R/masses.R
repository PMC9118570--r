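# Physical constants for peptide exact-mass arithmetic.

#' Monoisotopic residue masses and mass constants
#'
#' Standard IUPAC monoisotopic residue masses (Da) for the 20 proteinogenic
#' amino acids, plus the constants used throughout the exact-mass
#' calculations. `MASS_PROTON` is the physical proton mass used to convert
#' neutral masses to m/z; `MASS_C13_SHIFT` and `MASS_N15_SHIFT` are the
#' per-atom mass increments for a 13C and 15N substitution respectively, and
#' `MASS_C13_SHIFT` is also the spacing between adjacent isotopologue peaks
#' of a singly charged ion.
#'
#' @format Named numeric vector (`AA_MONO_MASS`) or length-one numerics.
#' @name mass-constants
#' @keywords internal
NULL

AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.0072765
MASS_C13_SHIFT <- 1.0033548
MASS_N15_SHIFT <- 0.9970349

#' Monoisotopic mass of a peptide
#'
#' Sums standard residue monoisotopic masses over a 1-letter amino-acid
#' sequence and adds one water for the free N- and C-termini. No
#' post-translational modifications are supported; isotope labels are
#' handled separately (see [label_mass_shift()]).
#'
#' @param sequence Character scalar, 1-letter amino-acid codes (the 20
#'   standard residues).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G")  # 75.03203
#' monoisotopic_mass("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
#' @export
monoisotopic_mass <- function(sequence) {
  residues <- .split_sequence(sequence)
  sum(AA_MONO_MASS[residues]) + MASS_WATER
}

# Validate and split a sequence into residue codes, naming any bad character.
.split_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a non-empty amino-acid string", call. = FALSE)
  }
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  unknown <- setdiff(unique(residues), names(AA_MONO_MASS))
  if (length(unknown) > 0L) {
    stop("unknown amino-acid residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  residues
}
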