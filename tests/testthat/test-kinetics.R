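# Non-steady-state isotope-dilution turnover estimation.

test_that("TTR follows its definition in both denominator modes", {
  expect_equal(compute_ttr(c(5, 100), c(100, 100)), c(0.05, 1))
  expect_equal(compute_ttr(5, 100, c_ffla = 5, denominator = "tracee"),
               5 / 90, tolerance = 1e-12)
  expect_warning(out <- compute_ttr(c(5, 5), c(100, 0)), "non-positive")
  expect_true(is.na(out[2]))
})

test_that("endogenous concentration is total minus tracers, flagged", {
  res <- endogenous_conc(100, 5, 5)
  expect_equal(res$c_endo_pg_ml, 90)
  expect_false(res$below_zero)
  res2 <- endogenous_conc(10, 6, 6)
  expect_equal(res2$c_endo_pg_ml, -2)
  expect_true(res2$below_zero)
  expect_equal(endogenous_conc(c(80, 90), c(0, 0), c(0, 0))$c_endo_pg_ml,
               c(80, 90))
  expect_error(endogenous_conc(100, 5), "required")
})

test_that("steady state collapses Ra and Rd to their algebraic forms", {
  time <- seq(0, 60, by = 10)
  series <- steady_state_series(time, k = 0.05, vd = 40, ra_endo = 18,
                                f_ff = 1, f_ffla = 1)
  prot <- constant_protocol(f_ff = 1, f_ffla = 1)
  ttr <- compute_ttr(series$c_ff_pg_ml, series$c_total_pg_ml)
  ra <- rate_of_appearance(prot, time, ttr, series$c_total_pg_ml,
                           vd_ml_kg = 40)
  expect_equal(nrow(ra), length(time) - 1L)
  expect_equal(ra$ra_pg_kg_min, rep(1 / ttr[1] - 2, nrow(ra)),
               tolerance = 1e-9)
  rd <- rate_of_disappearance(ra, prot, time, series$c_total_pg_ml, 40)
  expect_equal(rd$rd_pg_kg_min, ra$ra_pg_kg_min + 2, tolerance = 1e-9)
  # Rd = F_FF / TTR exactly at steady state
  expect_equal(rd$rd_pg_kg_min, rep(1 / ttr[1], nrow(rd)), tolerance = 1e-9)
})

test_that("the discretized appearance estimate matches a hand evaluation", {
  # TTR 0.05 -> 0.06 over 10 min, C constant 100, Vd 40, F_FF 1, F_FFLA 0
  prot <- constant_protocol(f_ff = 1, f_ffla = 0)
  ra <- rate_of_appearance(prot, time = c(0, 10), ttr = c(0.05, 0.06),
                           c_total = c(100, 100), vd_ml_kg = 40)
  expect_equal(ra$ra_pg_kg_min, 1 / 0.055 - 1 - 40 * 100 * 0.001 / 0.055,
               tolerance = 1e-9)  # -55.545...
  expect_identical(ra$flag, "negative")
})

test_that("the disappearance correction tracks the concentration derivative", {
  prot <- constant_protocol(f_ff = 1, f_ffla = 1)
  ra <- data.frame(t_mid_min = 5, ra_pg_kg_min = 18, flag = "")
  rd <- rate_of_disappearance(ra, prot, time = c(0, 10),
                              c_total = c(100, 90), vd_ml_kg = 40)
  expect_equal(rd$rd_pg_kg_min, 18 + 2 - 40 * (-1), tolerance = 1e-9)  # 60
  bad_ra <- data.frame(t_mid_min = 7, ra_pg_kg_min = 18, flag = "")
  expect_error(rate_of_disappearance(bad_ra, prot, c(0, 10), c(100, 90), 40),
               "grid")
})

test_that("degenerate protocols and grids are rejected", {
  prot0 <- infusion_protocol(tbw_kg = 70)
  expect_error(rate_of_appearance(prot0, c(0, 10), c(0.05, 0.05),
                                  c(100, 100), 40),
               "inconsistent")
  prot <- constant_protocol()
  expect_error(rate_of_appearance(prot, c(10, 0), c(0.05, 0.05),
                                  c(100, 100), 40),
               "increasing")
  expect_error(rate_of_appearance(prot, c(0, 10), c(0.05, 0.05),
                                  c(100, 100), vd_ml_kg = -1), "positive")
})

test_that("scaling the tracer dose self-consistently leaves Ra unchanged", {
  k <- 0.05; vd <- 40; ra_endo <- 140
  time <- seq(0, 30, by = 10)
  prot1 <- constant_protocol(f_ff = 4, f_ffla = 2)
  s1 <- steady_state_series(time, k, vd, ra_endo, 4, 2)
  ra1 <- rate_of_appearance(prot1, time,
                            compute_ttr(s1$c_ff_pg_ml, s1$c_total_pg_ml),
                            s1$c_total_pg_ml, vd)
  for (lambda in c(0.5, 3, 10)) {
    prot2 <- constant_protocol(f_ff = 4 * lambda, f_ffla = 2)
    s2 <- steady_state_series(time, k, vd, ra_endo, 4 * lambda, 2)
    ra2 <- rate_of_appearance(prot2, time,
                              compute_ttr(s2$c_ff_pg_ml, s2$c_total_pg_ml),
                              s2$c_total_pg_ml, vd)
    expect_equal(ra2$ra_pg_kg_min, ra1$ra_pg_kg_min, tolerance = 1e-9)
  }
})

test_that("the full-pipeline wrapper assembles consistent output", {
  truth <- postprandial_truth()
  ds <- simulate_kinetics(truth, init_tracers = "steady")
  res <- glucagon_kinetics(ds$noiseless, truth$protocol, vd_ml_kg = 40)
  expect_s3_class(res, "glucagon_kinetics")
  expect_identical(nrow(res$table), nrow(ds$noiseless) - 1L)
  expect_true(all(res$table$ttr > 0 & res$table$ttr <= 1))
  expect_true(all(res$series$c_endo_pg_ml > 0))
  expect_output(print(res), "Vd = 40.00 ml/kg")
})

test_that("Ra recovered at 1-min sampling tracks simulated truth within 5%", {
  truth <- postprandial_truth()
  ds <- simulate_kinetics(truth, init_tracers = "steady")
  res <- glucagon_kinetics(ds$noiseless, truth$protocol, vd_ml_kg = 40)
  t_all <- ds$noiseless$time_min
  ra_true <- (truth$ra_endo(t_all[-length(t_all)]) +
                truth$ra_endo(t_all[-1])) / 2
  mare <- mean(abs(res$table$ra_pg_kg_min - ra_true) / ra_true)
  expect_lt(mare, 0.05)
})
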