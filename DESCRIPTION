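Package: glucatrace
Title: Isotope-Dilution Mass-Spectrometry Workflow for Glucagon Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted mass-spectrometry quantitation and two-tracer turnover
    analysis for stable-isotope-labeled glucagon. Generates exact-mass SIM and
    PRM transition lists for 13C/15N-labeled glucagon species, fits
    area-ratio calibration curves with LOD/LOQ and QC precision rules,
    estimates glucagon rate of appearance and disappearance by the Steele
    non-steady-state isotope-dilution method from a primed two-tracer
    infusion, and fits the one-compartment volume of distribution from bolus
    decay. Includes a forward simulator that emulates plasma tracer time
    series and peak-area tables with realistic assay noise, providing ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
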