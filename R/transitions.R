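# SIM/PRM transition-list generation and CSV export.

#' Default transition-list layout
#'
#' Controls which ions the transition list contains. The defaults mirror the
#' published glucagon assay: SIM precursors at charge 4 with isotopologues
#' M+1..M+2 for the unlabeled species and M+0..M+2 for labeled species (the
#' unlabeled list starts at M+1; this offset is a per-species configuration,
#' not derived), and PRM b25/b26/b27 fragments at charge 3 with M+0 and M+1
#' per ion.
#'
#' @param precursor_charge Charge state for SIM precursor rows.
#' @param fragment_charge Charge state for PRM b-ion rows.
#' @param fragments Integer vector of b-ion lengths; empty vector suppresses
#'   the PRM block.
#' @param precursor_isotopologues_light,precursor_isotopologues_labeled
#'   Isotopologue indices for unlabeled / labeled species SIM rows.
#' @param fragment_isotopologues Isotopologue indices per fragment ion.
#' @param proton_mass Proton mass used in all m/z computations, Da.
#' @return A list of class `"transition_layout"`.
#' @export
transition_layout <- function(precursor_charge = 4L,
                              fragment_charge = 3L,
                              fragments = c(25L, 26L, 27L),
                              precursor_isotopologues_light = 1:2,
                              precursor_isotopologues_labeled = 0:2,
                              fragment_isotopologues = 0:1,
                              proton_mass = MASS_PROTON) {
  structure(list(precursor_charge = as.integer(precursor_charge),
                 fragment_charge = as.integer(fragment_charge),
                 fragments = as.integer(fragments),
                 precursor_isotopologues_light = as.integer(precursor_isotopologues_light),
                 precursor_isotopologues_labeled = as.integer(precursor_isotopologues_labeled),
                 fragment_isotopologues = as.integer(fragment_isotopologues),
                 proton_mass = proton_mass),
            class = "transition_layout")
}

#' Build a SIM/PRM transition table
#'
#' Emits one row per targeted ion: SIM (MS1) precursor isotopologues and PRM
#' (MS2) b-ion isotopologues for each species, at the charges and
#' isotopologue indices given by the layout. Rows are sorted by species (in
#' input order), then MS level, then ion.
#'
#' @param species A list of [peptide_species()] objects (e.g.
#'   [glucagon_species()]).
#' @param layout A [transition_layout()]; defaults mirror the published
#'   glucagon assay.
#' @return A data.frame with columns `species`, `ms_level` (`"MS1"`/`"MS2"`),
#'   `ion` (`"precursor"` or `"b<N>"`), `charge`, `isotopologue` (integer k
#'   of M+k), `mz`.
#' @examples
#' tt <- transition_table(glucagon_species())
#' subset(tt, ms_level == "MS1" & isotopologue == 0)
#' @export
transition_table <- function(species, layout = transition_layout()) {
  if (inherits(species, "peptide_species")) species <- list(species)
  if (length(species) == 0L) stop("no species supplied", call. = FALSE)
  rows <- lapply(species, function(sp) {
    stopifnot(inherits(sp, "peptide_species"))
    iso_pre <- if (length(sp$labels) == 0L) {
      layout$precursor_isotopologues_light
    } else {
      layout$precursor_isotopologues_labeled
    }
    ms1 <- data.frame(
      species = sp$name, ms_level = "MS1", ion = "precursor",
      charge = layout$precursor_charge, isotopologue = iso_pre,
      mz = precursor_mz(sp, layout$precursor_charge, iso_pre,
                        layout$proton_mass),
      stringsAsFactors = FALSE)
    ms2 <- do.call(rbind, lapply(layout$fragments, function(n) {
      data.frame(
        species = sp$name, ms_level = "MS2", ion = sprintf("b%d", n),
        charge = layout$fragment_charge,
        isotopologue = layout$fragment_isotopologues,
        mz = b_ion_mz(sp, n, layout$fragment_charge,
                      layout$fragment_isotopologues, layout$proton_mass),
        stringsAsFactors = FALSE)
    }))
    out <- rbind(ms1, ms2)
    out[order(out$ms_level, out$ion, out$isotopologue), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a transition list as CSV
#'
#' Column layout: `species, ms_level, ion, charge, isotopologue, mz` with m/z
#' written at 6 decimal places.
#'
#' @param transitions A data.frame from [transition_table()].
#' @param path Output CSV path.
#' @return `write_transition_csv` returns `path` invisibly;
#'   `read_transition_csv` returns the data.frame.
#' @export
write_transition_csv <- function(transitions, path) {
  out <- transitions
  out$mz <- sprintf("%.6f", out$mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(out, c("species", "ms_level", "ion", "charge",
                          "isotopologue", "mz"), path)
  out
}
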