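# Shared fixtures built in code.

# Steady-state concentrations implied by the one-compartment model for
# constant inputs: C = input_rate / (k * Vd), rates in pg/kg/min, Vd ml/kg.
steady_state_series <- function(time, k, vd, ra_endo, f_ff, f_ffla) {
  data.frame(
    time_min = time,
    c_ff_pg_ml = rep(f_ff / (k * vd), length(time)),
    c_ffla_pg_ml = rep(f_ffla / (k * vd), length(time)),
    c_total_pg_ml = rep((ra_endo + f_ff + f_ffla) / (k * vd), length(time))
  )
}

constant_protocol <- function(tbw = 70, f_ff = 1, f_ffla = 1, t_end = 1000,
                              bolus = 0) {
  infusion_protocol(
    tbw_kg = tbw, bolus_pg = bolus,
    f_ff = if (f_ff > 0) data.frame(t_start = 0, t_end = t_end, rate = f_ff),
    f_ffla = if (f_ffla > 0) data.frame(t_start = 0, t_end = t_end,
                                        rate = f_ffla))
}

# Postprandial recovery scenario: equilibrated constant two-tracer infusion
# with a gamma-like endogenous secretion pulse, sampled every minute.
postprandial_truth <- function(cv = c(ff = 0, ffla = 0, total = 0),
                               seed = 1L) {
  k <- 0.05; vd <- 40
  simulation_truth(
    vd_ml_kg = vd, k_per_min = k,
    ra_endo = postprandial_ra_profile(basal = 140, peak = 350, t_peak = 60),
    protocol = constant_protocol(f_ff = 8, f_ffla = 8, t_end = 351),
    sample_times_min = 0:350, cv = cv, seed = seed)
}
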