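# Forward simulator: one-compartment two-tracer plasma kinetics and
# peak-area tables with multiplicative assay noise. Provides ground truth
# for parameter-recovery tests; no raw spectra or chromatograms are
# simulated.

#' Gamma-like postprandial rate-of-appearance profile
#'
#' A smooth rise-and-return pulse emulating postprandial endogenous
#' glucagon secretion:
#' `Ra(t) = basal + (peak - basal) * (t/t_peak)^(t_peak/decay) *
#' exp((t_peak - t)/decay)`. The maximum is exactly `peak` at `t = t_peak`;
#' the profile equals `basal` at `t = 0` and relaxes back to `basal` with
#' tail scale `decay`. With `decay = t_peak` (the default) this is the
#' classic `(t/t_peak) * exp(1 - t/t_peak)` pulse, whose excess area is
#' `(peak - basal) * t_peak * e * gamma(2)`.
#'
#' @param basal Basal Ra, pg/kg/min.
#' @param peak Peak Ra, pg/kg/min (`>= basal`).
#' @param t_peak Time of the peak, min (> 0).
#' @param decay Tail time scale, min (> 0); default `t_peak`.
#' @return A vectorized function of time (min) returning Ra in pg/kg/min.
#' @export
postprandial_ra_profile <- function(basal, peak, t_peak, decay = t_peak) {
  if (basal < 0 || peak < basal || t_peak <= 0 || decay <= 0) {
    stop("require 0 <= basal <= peak and positive t_peak, decay",
         call. = FALSE)
  }
  a <- t_peak / decay
  function(t) {
    pulse <- ifelse(t <= 0, 0, (t / t_peak)^a * exp((t_peak - t) / decay))
    basal + (peak - basal) * pulse
  }
}

#' Define simulation ground truth
#'
#' Bundles everything the forward model needs: one-compartment parameters,
#' the endogenous secretion profile, the infusion protocol, the sampling
#' schedule and the per-channel assay noise. Defaults emulate the study
#' design: Vd 40 ml/kg and, with the default elimination rate, a basal
#' endogenous Ra giving a basal endogenous concentration of 70 pg/ml;
#' channel CVs follow the reported assay precision (about 5-6% for the MS
#' tracer channels, about 7% for the ELISA total).
#'
#' @param vd_ml_kg Volume of distribution, ml/kg.
#' @param k_per_min Elimination rate constant, 1/min.
#' @param ra_endo Endogenous Ra: a function of time (min) returning
#'   pg/kg/min, or a single number for a constant rate. Default: constant
#'   basal rate `k * Vd * 70` (basal endogenous concentration 70 pg/ml).
#' @param protocol An [infusion_protocol()]. Default: 70 kg subject, FF
#'   bolus sized to an initial tracer concentration of 50 pg/ml, constant
#'   FFLA infusion producing a steady-state concentration near 4 pg/ml.
#' @param sample_times_min Sampling schedule, min: default dense early
#'   post-bolus (1, 2, 3, 5, 7, 10, 15) then sparse to 350 min.
#' @param cv Named numeric, multiplicative noise CVs (fractions) for
#'   channels `ff`, `ffla`, `total`.
#' @param seed Integer RNG seed; the same truth always yields identical
#'   noisy output.
#' @return An object of class `"simulation_truth"`.
#' @export
simulation_truth <- function(vd_ml_kg = 40, k_per_min = 0.05,
                             ra_endo = NULL, protocol = NULL,
                             sample_times_min = c(1, 2, 3, 5, 7, 10, 15,
                                                  20, 30, 45, 60, 90, 120,
                                                  150, 180, 210, 240, 270,
                                                  300, 330, 350),
                             cv = c(ff = 0.055, ffla = 0.045, total = 0.07),
                             seed = 1L) {
  if (vd_ml_kg <= 0 || k_per_min <= 0) {
    stop("vd_ml_kg and k_per_min must be positive", call. = FALSE)
  }
  if (any(cv < 0)) stop("noise CVs must be >= 0", call. = FALSE)
  if (is.null(protocol)) {
    tbw <- 70
    protocol <- infusion_protocol(
      tbw_kg = tbw,
      bolus_pg = 50 * vd_ml_kg * tbw,  # C_FF(0+) = 50 pg/ml
      f_ffla = data.frame(t_start = 0, t_end = max(sample_times_min),
                          rate = 4 * k_per_min * vd_ml_kg))
  }
  if (is.null(ra_endo)) ra_endo <- k_per_min * vd_ml_kg * 70
  if (is.numeric(ra_endo)) {
    basal <- ra_endo
    ra_endo <- function(t) rep(basal, length(t))
  }
  cv <- cv[c("ff", "ffla", "total")]
  if (anyNA(cv)) stop("cv must name channels ff, ffla, total", call. = FALSE)
  structure(list(vd_ml_kg = vd_ml_kg, k_per_min = k_per_min,
                 ra_endo = ra_endo, protocol = protocol,
                 sample_times_min = sort(sample_times_min), cv = cv,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate a two-tracer plasma study
#'
#' Integrates the one-compartment tracer/tracee system with a fixed-step
#' fourth-order Runge-Kutta scheme on a fine grid:
#' `dC_endo/dt = Ra_endo(t)/Vd - k C_endo`,
#' `dC_ff/dt = F_ff(t)/Vd - k C_ff` (with the bolus as the initial FF
#' concentration `bolus / (Vd * TBW)`), and analogously for FFLA; the total
#' is the sum of the three pools. Samples are interpolated at the requested
#' times and multiplicative Gaussian noise (truncated at -3 SD so default
#' output stays positive) is applied per channel.
#'
#' @param truth A [simulation_truth()].
#' @param step_min Integration step, min; must not exceed the smallest
#'   sampling interval.
#' @param init_tracers `"bolus"` (tracers start at the bolus concentration
#'   only) or `"steady"` (tracer pools additionally start at the steady
#'   state of their t = 0 infusion rates, emulating an equilibrated primed
#'   infusion).
#' @param truncate_noise Truncate noise draws at -3 SD (default TRUE);
#'   disable to stress-test robustness to negative concentrations.
#' @return An object of class `"synthetic_dataset"`: list with `noiseless`
#'   and `noisy` plasma data.frames (`time_min`, `c_ff_pg_ml`,
#'   `c_ffla_pg_ml`, `c_total_pg_ml`, `c_endo_pg_ml`), `truth`, `ra_true`
#'   (function), and `fine` (the integration grid, for diagnostics).
#' @export
simulate_kinetics <- function(truth, step_min = 0.1,
                              init_tracers = c("bolus", "steady"),
                              truncate_noise = TRUE) {
  stopifnot(inherits(truth, "simulation_truth"))
  init_tracers <- match.arg(init_tracers)
  times <- truth$sample_times_min
  intervals <- diff(c(0, times))
  intervals <- intervals[intervals > 0]
  if (step_min > min(intervals)) {
    stop("integration step exceeds the smallest sampling interval",
         call. = FALSE)
  }
  p <- truth$protocol
  vd <- truth$vd_ml_kg; k <- truth$k_per_min
  t_end <- max(times)
  grid <- seq(0, t_end, by = step_min)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  c_ff0 <- p$bolus_pg / (vd * p$tbw_kg)
  c_ffla0 <- 0
  if (init_tracers == "steady") {
    c_ff0 <- c_ff0 + infusion_rate(p, 0, "ff") / (k * vd)
    c_ffla0 <- infusion_rate(p, 0, "ffla") / (k * vd)
  }
  c_endo0 <- truth$ra_endo(0) / (k * vd)

  deriv <- function(t, y) {
    c(truth$ra_endo(t) / vd - k * y[1L],
      infusion_rate(p, t, "ff") / vd - k * y[2L],
      infusion_rate(p, t, "ffla") / vd - k * y[3L])
  }
  y <- matrix(NA_real_, nrow = length(grid), ncol = 3L)
  y[1L, ] <- c(c_endo0, c_ff0, c_ffla0)
  for (i in seq_len(length(grid) - 1L)) {
    h <- grid[i + 1L] - grid[i]
    yi <- y[i, ]; ti <- grid[i]
    k1 <- deriv(ti, yi)
    k2 <- deriv(ti + h / 2, yi + h / 2 * k1)
    k3 <- deriv(ti + h / 2, yi + h / 2 * k2)
    k4 <- deriv(ti + h, yi + h * k3)
    y[i + 1L, ] <- yi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  sample_channel <- function(col) stats::approx(grid, y[, col], xout = times)$y
  noiseless <- data.frame(
    time_min = times,
    c_ff_pg_ml = sample_channel(2L),
    c_ffla_pg_ml = sample_channel(3L),
    c_endo_pg_ml = sample_channel(1L))
  noiseless$c_total_pg_ml <- noiseless$c_endo_pg_ml +
    noiseless$c_ff_pg_ml + noiseless$c_ffla_pg_ml

  set.seed(truth$seed)
  draw <- function(n, cv) {
    z <- stats::rnorm(n)
    if (truncate_noise) z <- pmax(z, -3)
    1 + cv * z
  }
  n <- nrow(noiseless)
  noisy <- noiseless
  noisy$c_ff_pg_ml <- noiseless$c_ff_pg_ml * draw(n, truth$cv[["ff"]])
  noisy$c_ffla_pg_ml <- noiseless$c_ffla_pg_ml * draw(n, truth$cv[["ffla"]])
  noisy$c_total_pg_ml <- noiseless$c_total_pg_ml * draw(n, truth$cv[["total"]])
  noisy$c_endo_pg_ml <- noisy$c_total_pg_ml - noisy$c_ff_pg_ml -
    noisy$c_ffla_pg_ml

  structure(list(noiseless = noiseless[, c("time_min", "c_ff_pg_ml",
                                           "c_ffla_pg_ml", "c_total_pg_ml",
                                           "c_endo_pg_ml")],
                 noisy = noisy[, c("time_min", "c_ff_pg_ml", "c_ffla_pg_ml",
                                   "c_total_pg_ml", "c_endo_pg_ml")],
                 truth = truth, ra_true = truth$ra_endo,
                 fine = data.frame(time_min = grid, c_endo_pg_ml = y[, 1L],
                                   c_ff_pg_ml = y[, 2L],
                                   c_ffla_pg_ml = y[, 3L])),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic two-tracer plasma dataset\n")
  cat(sprintf("  %d samples over %g-%g min; Vd = %g ml/kg, k = %g /min, seed %d\n",
              nrow(x$noisy), min(x$noisy$time_min), max(x$noisy$time_min),
              x$truth$vd_ml_kg, x$truth$k_per_min, x$truth$seed))
  cat(sprintf("  noise CVs: FF %.1f%%, FFLA %.1f%%, total %.1f%%\n",
              100 * x$truth$cv[["ff"]], 100 * x$truth$cv[["ffla"]],
              100 * x$truth$cv[["total"]]))
  invisible(x)
}

#' Simulate calibration / QC peak-area tables
#'
#' Emulates the integrated-peak-area tables the quantitation stage consumes:
#' for each concentration level, replicate and day, an internal-standard
#' area with multiplicative noise and an analyte area
#' `slope * conc * is_area * (1 + cv * z)`, so that the expected area ratio
#' is `slope * conc`. The default response slope of 0.02 per pg/ml makes the
#' area ratio 1 at the 50 pg/ml internal-standard level.
#'
#' @param concentrations_pg_ml Numeric vector of nominal levels (e.g. the
#'   seven-point tracer ladder `c(1.56, 3.125, 6.25, 12.5, 25, 50, 100)`).
#' @param species Species name recorded in the table.
#' @param slope Response slope, ratio units per pg/ml.
#' @param cv Multiplicative noise CV (fraction) applied independently to IS
#'   and analyte areas.
#' @param replicates Replicates per level per day.
#' @param days Number of batches/days.
#' @param is_area Nominal internal-standard area (arbitrary counts).
#' @param snr_per_pg_ml Signal-to-noise recorded per pg/ml of analyte.
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `species`, `level_id`,
#'   `nominal_pg_ml`, `day`, `replicate`, `analyte_area`, `is_area`, `snr`.
#' @export
simulate_calibration <- function(concentrations_pg_ml =
                                   c(1.56, 3.125, 6.25, 12.5, 25, 50, 100),
                                 species = "FF", slope = 0.02, cv = 0.05,
                                 replicates = 3L, days = 1L, is_area = 1e5,
                                 snr_per_pg_ml = 3, seed = 1L) {
  if (slope <= 0) stop("response slope must be positive", call. = FALSE)
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  set.seed(seed)
  conc <- sort(concentrations_pg_ml)
  grid <- expand.grid(replicate = seq_len(replicates), day = seq_len(days),
                      level = seq_along(conc))
  n <- nrow(grid)
  z_is <- pmax(stats::rnorm(n), -3)
  z_an <- pmax(stats::rnorm(n), -3)
  is_obs <- is_area * (1 + cv * z_is)
  nominal <- conc[grid$level]
  analyte <- slope * nominal * is_obs * (1 + cv * z_an)
  data.frame(species = species,
             level_id = sprintf("Std%d", grid$level),
             nominal_pg_ml = nominal,
             day = grid$day, replicate = grid$replicate,
             analyte_area = analyte, is_area = is_obs,
             snr = snr_per_pg_ml * nominal * (1 + cv * z_an),
             stringsAsFactors = FALSE)
}
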