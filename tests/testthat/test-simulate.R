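# Forward simulator: ODE correctness, noise model, determinism.

test_that("bolus-only decay matches the closed form", {
  prot <- infusion_protocol(tbw_kg = 70, bolus_pg = 1.4e5)
  truth <- simulation_truth(vd_ml_kg = 40, k_per_min = 0.05,
                            ra_endo = 0, protocol = prot,
                            cv = c(ff = 0, ffla = 0, total = 0), seed = 1)
  ds <- simulate_kinetics(truth)
  t <- ds$noiseless$time_min
  closed <- (1.4e5 / (40 * 70)) * exp(-0.05 * t)
  expect_equal(ds$noiseless$c_ff_pg_ml, closed, tolerance = 1e-6)
  expect_equal(ds$noiseless$c_ffla_pg_ml, rep(0, length(t)))
  expect_equal(ds$noiseless$c_endo_pg_ml, rep(0, length(t)),
               tolerance = 1e-12)
})

test_that("constant infusion plateaus at F / (k * Vd)", {
  k <- 0.05; vd <- 40; rate <- 8
  prot <- infusion_protocol(tbw_kg = 70,
                            f_ff = data.frame(t_start = 0, t_end = 400,
                                              rate = rate))
  truth <- simulation_truth(vd_ml_kg = vd, k_per_min = k, ra_endo = 0,
                            protocol = prot,
                            sample_times_min = c(10, 7 / k, 350),
                            cv = c(ff = 0, ffla = 0, total = 0), seed = 1)
  ds <- simulate_kinetics(truth)
  plateau <- rate / (k * vd)
  late <- ds$noiseless$time_min >= 7 / k
  expect_equal(ds$noiseless$c_ff_pg_ml[late],
               rep(plateau, sum(late)), tolerance = 1e-3)
  expect_lt(ds$noiseless$c_ff_pg_ml[1], plateau)
})

test_that("same seed reproduces noisy output exactly; zero CV is noiseless", {
  truth <- simulation_truth(seed = 99)
  a <- simulate_kinetics(truth)
  b <- simulate_kinetics(truth)
  expect_identical(a$noisy, b$noisy)
  truth0 <- simulation_truth(seed = 99, cv = c(ff = 0, ffla = 0, total = 0))
  c <- simulate_kinetics(truth0)
  expect_equal(c$noisy, c$noiseless, tolerance = 1e-12)
})

test_that("postprandial profile hits basal, peak, and its closed-form area", {
  f <- postprandial_ra_profile(basal = 140, peak = 350, t_peak = 60)
  expect_equal(f(0), 140)
  expect_equal(f(60), 350)
  expect_lt(abs(f(1e5) - 140), 1e-8)
  grid <- seq(0, 3000, by = 0.05)
  excess <- sum((f(grid) - 140)) * 0.05
  expect_equal(excess, (350 - 140) * 60 * exp(1) * gamma(2),
               tolerance = 0.005)
  # the peak stays at t_peak for other tail scales
  g <- postprandial_ra_profile(100, 400, 45, decay = 90)
  expect_equal(g(45), 400)
  expect_lt(g(44), 400)
  expect_error(postprandial_ra_profile(100, 50, 60), "basal <= peak")
})

test_that("simulated tracer mass is conserved", {
  prot <- infusion_protocol(tbw_kg = 70, bolus_pg = 1.4e5,
                            f_ff = data.frame(t_start = 30, t_end = 90,
                                              rate = 8))
  truth <- simulation_truth(vd_ml_kg = 40, k_per_min = 0.05, ra_endo = 0,
                            protocol = prot,
                            sample_times_min = c(10, 350),
                            cv = c(ff = 0, ffla = 0, total = 0), seed = 1)
  ds <- simulate_kinetics(truth)
  fine <- ds$fine
  h <- diff(fine$time_min)
  auc <- sum((fine$c_ff_pg_ml[-1] + fine$c_ff_pg_ml[-nrow(fine)]) / 2 * h)
  eliminated <- 0.05 * 40 * auc               # pg/kg
  input <- 1.4e5 / 70 + 8 * (90 - 30)         # pg/kg
  expect_equal(eliminated, input, tolerance = 0.005)
})

test_that("simulated QC batches reproduce the assay's precision envelope", {
  set.seed(1)
  intra <- vapply(1:200, function(seed) {
    tab <- simulate_calibration(concentrations_pg_ml = 13.33, cv = 0.055,
                                replicates = 3, days = 3, seed = seed)
    curve_tab <- simulate_calibration(cv = 0.055, seed = seed + 10000L)
    curve <- fit_calibration(curve_tab)
    meas <- inverse_predict(curve, area_ratio(tab$analyte_area,
                                              tab$is_area))$conc_pg_ml
    qc_precision(data.frame(day = tab$day,
                            measured_pg_ml = meas))$intra_day_cv_pct
  }, numeric(1))
  expect_gt(mean(intra), 2)
  expect_lt(mean(intra), 10)
  expect_gt(mean(intra >= 2 & intra <= 10), 0.9)
})

test_that("calibration simulator validates inputs and recovers the slope", {
  tab <- simulate_calibration(cv = 0, seed = 1)
  curve <- fit_calibration(tab)
  expect_equal(curve$slope, 0.02, tolerance = 1e-9)
  expect_equal(curve$r, 1, tolerance = 1e-9)
  expect_error(simulate_calibration(slope = -1), "positive")
  expect_error(simulate_kinetics(simulation_truth(), step_min = 5),
               "step exceeds")
})
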