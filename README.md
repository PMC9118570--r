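# glucatrace

Targeted mass-spectrometry quantitation and two-tracer turnover analysis for
stable-isotope-labeled glucagon.

Circulating glucagon reflects a balance of secretion, distribution and
clearance that cannot be resolved from concentration measurements alone. A
two-tracer isotope-dilution design solves this: two ¹³C/¹⁵N-labeled glucagon
analogues (an "FF" tracer labeled at Phe6 and Phe22, and an "FFLA" tracer
labeled at Phe6, Leu14, Ala19 and Phe22) are infused into a subject, measured
in plasma by antibody enrichment plus targeted LC–MS/MS against a third
labeled analogue ("F22") used as internal standard, while an ELISA measures
total glucagon (endogenous + tracers). The dilution of tracer by endogenous
secretion then yields glucagon kinetics. `glucatrace` implements the whole
desk side of that workflow for analysts running such studies:

1. **Transition lists** (`transition_table()`): exact monoisotopic m/z for
   SIM precursors (z = 4) and PRM b25/b26/b27 fragments (z = 3) of all four
   glucagon species, from the 29-mer sequence
   `HSQGTFTSDYSKYLDSRRAQDFVQWLMNT` and residue label stoichiometries alone.
2. **Quantitation** (`fit_calibration()`, `inverse_predict()`,
   `evaluate_lod()`, `evaluate_loq()`, `qc_precision()`): analyte/IS
   area-ratio calibration, back-calculation in pg/ml, and the standard
   bioanalytical acceptance rules (S/N ≥ 3 and blank + 3 SD for LOD;
   CV ≤ 25 % and RE ≤ 25 % for LOQ; intra-/inter-day CV for QC).
3. **Kinetics** (`glucagon_kinetics()`, `fit_vd()`): Steele's
   non-steady-state isotope-dilution estimator on consecutive-sample
   intervals,

   Ra = F_FF/TTR̄ − F_FF − F_FFLA − V_d·C̄·(ΔTTR/Δt)/TTR̄
   Rd = Ra + F_FF + F_FFLA − V_d·(ΔC/Δt)

   with TTR the FF-tracer-to-total ratio, all rates in pg/kg/min and V_d in
   ml/kg (fitted from mono-exponential bolus decay, C(t) = C₀e^(−kt),
   V_d = dose/C₀/TBW).
4. **Simulation** (`simulate_kinetics()`, `simulate_calibration()`): a
   one-compartment forward model with multiplicative assay noise that
   generates plasma time series and peak-area tables with known ground
   truth, so every stage is testable end to end without instrument data.

## Worked example

```r
library(glucatrace)

## 1. Transition list for the four species
sp <- glucagon_species()
head(subset(transition_table(sp), ms_level == "MS1"), 5)
#  species ms_level       ion charge isotopologue       mz
#    light      MS1 precursor      4            1 871.4120
#    light      MS1 precursor      4            2 871.6629
#      F22      MS1 precursor      4            0 873.6680
#      F22      MS1 precursor      4            1 873.9188
#      F22      MS1 precursor      4            2 874.1697

## 2. Calibration on a simulated seven-level peak-area table (5 % CV)
curve <- fit_calibration(simulate_calibration(cv = 0.05, days = 3, seed = 42))
curve
# Area-ratio calibration curve (FF)
#   ratio = 0.0036978 + 0.019659 * conc [pg/ml]   (weighting: none)
#   r = 1.0000 over 7 levels (1.56-100 pg/ml)

## 3. Two-tracer turnover on a simulated study (FF bolus + FFLA infusion)
truth <- simulation_truth(seed = 42)        # Vd 40 ml/kg, k 0.05/min
ds <- simulate_kinetics(truth)
res <- glucagon_kinetics(ds$noisy, truth$protocol, decay_window = c(0, 60))
res
# Two-tracer glucagon turnover analysis
#   21 samples, 20 intervals, t = 1-350 min
#   Vd = 39.11 ml/kg (fitted from bolus decay)
#   median Ra = 121.08, median Rd = 134.73 pg/kg/min (17/20 clean intervals)
res$vd_fit
# One-compartment bolus-decay fit
#   C0 = 51.14 pg/ml (SE 0.87), k = 0.04951 /min (SE 0.0022)
#   Vd = 39.11 ml/kg (SE 0.67), half-life = 14 min
#   residual SD 1.35 pg/ml on 11 points
```

The transition m/z values are the assay's published monitoring targets; the
calibration slope ~0.02/pg/ml reflects the 50 pg/ml internal standard
(ratio 1 at 50 pg/ml); the fitted V_d of 39.1 ml/kg recovers the simulated
truth of 40 ml/kg from noisy data; and the median appearance rate of about
121 pg/kg/min recovers the simulated basal endogenous secretion (140
pg/kg/min gives 70 pg/ml at this V_d and k; estimates from noisy 10–30 min
sampling intervals scatter around it).

A thin command-line front end over the same functions lives at
`inst/cli/glucatrace.R` (subcommands `transitions`, `calibrate`, `kinetics`,
`simulate`, `recover`).

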