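# Exact-mass arithmetic for labeled glucagon species.

test_that("monoisotopic masses match independent reference values", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(GLUCAGON_SEQUENCE), 3480.6157,
               tolerance = 1e-6)
  expect_error(monoisotopic_mass(""), "non-empty")
  expect_error(monoisotopic_mass("HSQGTXZ"), "X")
})

test_that("label mass shifts follow per-atom isotope arithmetic", {
  phe <- list(isotope_label("C", 9), isotope_label("N", 1))
  expect_equal(label_mass_shift(phe), 10.02722, tolerance = 1e-6)
  sp <- glucagon_species()
  expect_equal(species_label_shift(sp$FFLA), 30.08168, tolerance = 1e-6)
  expect_equal(species_label_shift(sp$FF), 2 * 10.0272281, tolerance = 1e-7)
  expect_identical(label_mass_shift(list()), 0)
  expect_error(isotope_label("C", -1), "non-negative")
  expect_error(isotope_label("Xe", 2), "per_atom_shift")
})

test_that("built-in species carry the expected sequence and label positions", {
  sp <- glucagon_species()
  for (s in sp) expect_identical(s$sequence, "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
  expect_identical(names(sp$FF$labels), c("6", "22"))
  expect_identical(names(sp$FFLA$labels), c("6", "14", "19", "22"))
  expect_identical(names(sp$F22$labels), "22")
  expected_residue <- c(`6` = "F", `14` = "L", `19` = "A", `22` = "F")
  for (p in names(sp$FFLA$labels)) {
    expect_identical(substr(sp$FFLA$sequence, as.integer(p), as.integer(p)),
                     expected_residue[[p]])
  }
  expect_error(peptide_species("bad", "GAS", list(`9` = list())),
               "within")
})

test_that("precursor m/z reproduces the published SIM targets", {
  sp <- glucagon_species()
  expect_equal(precursor_mz(sp$FF, 4), 876.17, tolerance = 0.01)
  expect_equal(precursor_mz(sp$FFLA, 4), 878.68, tolerance = 0.01)
  expect_equal(precursor_mz(sp$F22, 4), 873.67, tolerance = 0.01)
  expect_equal(precursor_mz(sp$light, 4, 1), 871.41, tolerance = 0.01)
  expect_error(precursor_mz(sp$light, 0), "charge")
})

test_that("isotopologue spacing is exactly 1.0033548 / charge", {
  sp <- glucagon_species()
  for (s in sp) {
    for (z in c(1L, 3L, 4L)) {
      spacing <- diff(precursor_mz(s, z, 0:4))
      expect_equal(spacing, rep(1.0033548 / z, 4), tolerance = 1e-12)
    }
  }
  expect_equal(precursor_mz(sp$light, 4, 1) - precursor_mz(sp$light, 4, 0),
               1.0033548 / 4, tolerance = 1e-9)
})

test_that("b-ion m/z reproduces the published PRM targets", {
  sp <- glucagon_species()
  # frozen published values; cells inconsistent with label arithmetic are
  # deliberately absent (b26 FF, b27 FFLA)
  published <- list(
    list("light", 25, 1002.14), list("F22", 25, 1005.48),
    list("FF", 25, 1008.82), list("FFLA", 25, 1012.17),
    list("light", 26, 1039.83), list("F22", 26, 1043.18),
    list("FFLA", 26, 1049.86),
    list("light", 27, 1083.51), list("F22", 27, 1086.86),
    list("FF", 27, 1090.20)
  )
  for (row in published) {
    expect_equal(b_ion_mz(sp[[row[[1]]]], row[[2]], 3), row[[3]],
                 tolerance = 0.01,
                 label = sprintf("%s b%d", row[[1]], row[[2]]))
  }
  expect_error(b_ion_mz(sp$light, 29, 3), "fragment length")
  expect_error(b_ion_mz(sp$light, 0, 3), "fragment length")
})

test_that("b-ion series is monotone and label shifts propagate into fragments", {
  sp <- glucagon_species()
  for (z in c(2L, 3L)) {
    series <- vapply(1:28, function(n) b_ion_mz(sp$light, n, z), numeric(1))
    expect_true(all(diff(series) > 0))
  }
  # labeled minus light equals the in-fragment label shift over charge
  for (n in c(5L, 6L, 13L, 14L, 18L, 19L, 21L, 22L, 28L)) {
    for (s in c("F22", "FF", "FFLA")) {
      expect_equal(
        b_ion_mz(sp[[s]], n, 3) - b_ion_mz(sp$light, n, 3),
        species_label_shift(sp[[s]], n) / 3, tolerance = 1e-9)
    }
  }
  # position 6 label enters FF fragments from b6 onward only
  expect_equal(b_ion_mz(sp$FF, 5, 3), b_ion_mz(sp$light, 5, 3),
               tolerance = 1e-12)
  expect_gt(b_ion_mz(sp$FF, 6, 3) - b_ion_mz(sp$light, 6, 3), 3)
})

test_that("transition table honours layout and spacing invariants", {
  sp <- glucagon_species()
  tt <- transition_table(sp)
  # default layout: light 2 SIM rows, labeled 3; 3 fragments x 2 isotopologues
  expect_identical(nrow(tt), 2L + 3L * 3L + 4L * 6L)
  ms1 <- tt[tt$ms_level == "MS1", ]
  expect_equal(min(ms1$mz[ms1$species == "light"]), 871.41, tolerance = 0.01)
  expect_equal(min(ms1$mz[ms1$species == "F22"]), 873.67, tolerance = 0.01)
  # spacing within every (species, ion, charge) group
  for (key in split(tt, interaction(tt$species, tt$ion, drop = TRUE))) {
    key <- key[order(key$isotopologue), ]
    if (nrow(key) > 1L) {
      expect_equal(diff(key$mz),
                   diff(key$isotopologue) * 1.0033548 / key$charge[1L],
                   tolerance = 1e-6)
    }
  }
  one <- transition_table(sp["FF"],
                          transition_layout(fragments = integer(0),
                                            precursor_isotopologues_labeled = 0L))
  expect_identical(nrow(one), 1L)
  expect_error(transition_table(list()), "no species")
})

test_that("transition CSV round-trips", {
  tt <- transition_table(glucagon_species())
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(tt, path)
  back <- read_transition_csv(path)
  expect_identical(back$species, tt$species)
  expect_equal(back$mz, tt$mz, tolerance = 1e-6)
})

test_that("species can be defined from config label triples", {
  cfg <- list(
    FF = list(),  # built-in
    custom = list(sequence = GLUCAGON_SEQUENCE,
                  labels = c("6:C:9", "6:N:1", "22:C:9", "22:N:1"))
  )
  sp <- species_from_config(cfg)
  expect_equal(precursor_mz(sp$custom, 4), precursor_mz(sp$FF, 4),
               tolerance = 1e-12)
  expect_error(species_from_config(list(x = list(sequence = "GAS",
                                                 labels = "6:C"))),
               "triple")
})
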