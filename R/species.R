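# Isotopically labeled glucagon species and their ion m/z arithmetic.

GLUCAGON_SEQUENCE <- "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT"

#' Define an isotope label
#'
#' A residue-level stable-isotope substitution: `heavy_count` atoms of
#' `element` replaced by the heavy isotope, each adding `per_atom_shift` Da.
#' Defaults cover the two labels used in the glucagon tracers
#' (13C: +1.0033548 Da/atom, 15N: +0.9970349 Da/atom).
#'
#' @param element Element symbol, `"C"` or `"N"` for the built-in shifts.
#' @param heavy_count Non-negative integer number of substituted atoms.
#' @param per_atom_shift Mass increment per substituted atom, Da. Defaults to
#'   the 13C or 15N shift according to `element`.
#' @return An object of class `"isotope_label"`.
#' @examples
#' isotope_label("C", 9)  # 13C9 phenylalanine ring + chain carbons
#' isotope_label("N", 1)
#' @export
isotope_label <- function(element, heavy_count,
                          per_atom_shift = switch(element,
                                                  C = MASS_C13_SHIFT,
                                                  N = MASS_N15_SHIFT,
                                                  NA_real_)) {
  if (length(heavy_count) != 1L || is.na(heavy_count) || heavy_count < 0 ||
      heavy_count != round(heavy_count)) {
    stop("heavy_count must be a non-negative integer", call. = FALSE)
  }
  if (is.na(per_atom_shift) || per_atom_shift <= 0) {
    stop("per_atom_shift must be positive (supply it for elements other ",
         "than C/N)", call. = FALSE)
  }
  structure(list(element = element, heavy_count = as.integer(heavy_count),
                 per_atom_shift = per_atom_shift),
            class = "isotope_label")
}

#' Total mass shift of a set of isotope labels
#'
#' @param labels A list of [isotope_label()] objects (possibly empty).
#' @return Summed mass shift in Da; 0 for an empty list.
#' @examples
#' # one 13C9,15N1 phenylalanine:
#' label_mass_shift(list(isotope_label("C", 9), isotope_label("N", 1)))
#' @export
label_mass_shift <- function(labels) {
  if (length(labels) == 0L) return(0)
  if (inherits(labels, "isotope_label")) labels <- list(labels)
  sum(vapply(labels, function(l) {
    stopifnot(inherits(l, "isotope_label"))
    l$heavy_count * l$per_atom_shift
  }, numeric(1)))
}

# Residue-specific label sets used by the built-in tracers.
.label_phe <- function() list(isotope_label("C", 9), isotope_label("N", 1))
.label_leu <- function() list(isotope_label("C", 6), isotope_label("N", 1))
.label_ala <- function() list(isotope_label("C", 3))

#' Define a peptide species with residue-indexed isotope labels
#'
#' @param name Identifier for the species.
#' @param sequence 1-letter amino-acid sequence.
#' @param labels Named list mapping 1-based residue positions (names,
#'   coercible to integer) to lists of [isotope_label()] objects.
#' @return An object of class `"peptide_species"`.
#' @seealso [glucagon_species()] for the four built-in glucagon species.
#' @export
peptide_species <- function(name, sequence, labels = list()) {
  residues <- .split_sequence(sequence)
  if (length(labels) > 0L) {
    pos <- as.integer(names(labels))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(residues))) {
      stop("label positions must be within [1, ", length(residues), "]",
           call. = FALSE)
    }
  }
  structure(list(name = name, sequence = toupper(sequence), labels = labels),
            class = "peptide_species")
}

#' @export
print.peptide_species <- function(x, ...) {
  cat("Peptide species:", x$name, "\n")
  cat("  sequence:", x$sequence, "(", nchar(x$sequence), "residues )\n")
  if (length(x$labels) > 0L) {
    for (p in names(x$labels)) {
      lab <- vapply(x$labels[[p]], function(l)
        sprintf("%s x%d", l$element, l$heavy_count), character(1))
      cat(sprintf("  label @%s (%s): %s\n", p,
                  substr(x$sequence, as.integer(p), as.integer(p)),
                  paste(lab, collapse = ", ")))
    }
  } else cat("  unlabeled\n")
  cat(sprintf("  monoisotopic mass: %.4f Da (+%.5f label shift)\n",
              monoisotopic_mass(x$sequence), species_label_shift(x)))
  invisible(x)
}

#' Built-in glucagon species
#'
#' The four glucagon species used in the two-tracer isotope-dilution assay:
#' unlabeled (`"light"`) glucagon; the single-label internal standard
#' (`"F22"`: Phe22 13C9,15N1); the FF tracer (`"FF"`: Phe6 + Phe22, each
#' 13C9,15N1); and the FFLA tracer (`"FFLA"`: Phe6, Phe22 13C9,15N1 plus
#' Leu14 13C6,15N1 and Ala19 13C3). All share the 29-residue glucagon
#' sequence.
#'
#' @param which Character vector of species names to return; default all four.
#' @return A named list of [peptide_species()] objects.
#' @examples
#' sp <- glucagon_species()
#' names(sp)
#' @export
glucagon_species <- function(which = c("light", "F22", "FF", "FFLA")) {
  builders <- list(
    light = function() peptide_species("light", GLUCAGON_SEQUENCE),
    F22 = function() peptide_species("F22", GLUCAGON_SEQUENCE,
                                     list(`22` = .label_phe())),
    FF = function() peptide_species("FF", GLUCAGON_SEQUENCE,
                                    list(`6` = .label_phe(),
                                         `22` = .label_phe())),
    FFLA = function() peptide_species("FFLA", GLUCAGON_SEQUENCE,
                                      list(`6` = .label_phe(),
                                           `14` = .label_leu(),
                                           `19` = .label_ala(),
                                           `22` = .label_phe()))
  )
  bad <- setdiff(which, names(builders))
  if (length(bad) > 0L) {
    stop("unknown built-in species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lapply(stats::setNames(nm = which), function(w) builders[[w]]())
}

#' Total label mass shift of a species
#'
#' @param species A [peptide_species()] object.
#' @param max_position Only count labels at residue positions `<=
#'   max_position` (used for fragment ions); default the full sequence.
#' @return Summed label shift in Da.
#' @export
species_label_shift <- function(species, max_position = nchar(species$sequence)) {
  if (length(species$labels) == 0L) return(0)
  pos <- as.integer(names(species$labels))
  keep <- pos <= max_position
  if (!any(keep)) return(0)
  sum(vapply(species$labels[keep], label_mass_shift, numeric(1)))
}

#' Precursor (intact peptide) m/z
#'
#' m/z of the protonated intact species at a given charge and isotopologue:
#' `(M + label shift + z * m_proton + k * 1.0033548) / z`, where `M` is the
#' unlabeled monoisotopic mass and `k` the isotopologue index (M+k).
#'
#' @param species A [peptide_species()] object.
#' @param charge Positive integer charge state.
#' @param isotopologue Non-negative integer isotopologue index (0 = M+0).
#' @param proton_mass Proton mass in Da (default the physical value
#'   1.0072765).
#' @return m/z in Da per unit charge. Vectorized over `isotopologue`.
#' @examples
#' sp <- glucagon_species()
#' precursor_mz(sp$FF, charge = 4)          # 876.17
#' precursor_mz(sp$light, charge = 4, isotopologue = 1)  # 871.41
#' @export
precursor_mz <- function(species, charge, isotopologue = 0,
                         proton_mass = MASS_PROTON) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  if (any(isotopologue < 0)) {
    stop("isotopologue index must be non-negative", call. = FALSE)
  }
  m <- monoisotopic_mass(species$sequence) + species_label_shift(species)
  (m + charge * proton_mass + isotopologue * MASS_C13_SHIFT) / charge
}

#' b-ion fragment m/z
#'
#' m/z of the N-terminal b-ion containing the first `n` residues:
#' `(sum of residue masses 1..n + label shifts at positions <= n +
#' z * m_proton + k * 1.0033548) / z`. b-ions carry no terminal water.
#'
#' @inheritParams precursor_mz
#' @param n Fragment length in residues, `1 <= n < sequence length`.
#' @return m/z in Da per unit charge. Vectorized over `isotopologue`.
#' @examples
#' sp <- glucagon_species()
#' b_ion_mz(sp$light, n = 25, charge = 3)  # 1002.14
#' b_ion_mz(sp$FF, n = 25, charge = 3)     # 1008.82: both Phe labels in b25
#' @export
b_ion_mz <- function(species, n, charge, isotopologue = 0,
                     proton_mass = MASS_PROTON) {
  len <- nchar(species$sequence)
  if (length(n) != 1L || is.na(n) || n < 1 || n >= len || n != round(n)) {
    stop("fragment length n must satisfy 1 <= n < ", len, call. = FALSE)
  }
  if (length(charge) != 1L || is.na(charge) || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  if (any(isotopologue < 0)) {
    stop("isotopologue index must be non-negative", call. = FALSE)
  }
  residues <- .split_sequence(substr(species$sequence, 1L, n))
  m <- sum(AA_MONO_MASS[residues]) + species_label_shift(species, n)
  (m + charge * proton_mass + isotopologue * MASS_C13_SHIFT) / charge
}
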