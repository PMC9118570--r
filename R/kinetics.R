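# Two-tracer non-steady-state isotope-dilution turnover: TTR, Ra, Rd.
#
# Unit convention (used consistently everywhere): concentrations pg/ml,
# infusion rates and turnover rates pg/kg/min, volume of distribution Vd in
# ml/kg. Under this convention both the appearance correction
# Vd * C * (dTTR/dt) / TTRbar and the disappearance correction
# Vd * (dC/dt) come out in pg/kg/min with no explicit body-weight division:
# expressing the distribution volume per kg absorbs it.

#' Tracer-tracee ratio series
#'
#' Elementwise ratio of FF tracer concentration to total glucagon
#' concentration (the working definition of TTR in this assay, where the
#' denominator is the ELISA total: endogenous + tracers). The classical
#' tracer-to-tracee alternative, FF / (total - FF - FFLA), is available
#' with `denominator = "tracee"`.
#'
#' @param c_ff FF tracer concentration, pg/ml.
#' @param c_total Total glucagon concentration, pg/ml.
#' @param c_ffla FFLA concentration, pg/ml (required for `"tracee"` mode).
#' @param denominator `"total"` (default) or `"tracee"`.
#' @return Numeric TTR series; NA (with a warning) where the denominator is
#'   not positive.
#' @export
compute_ttr <- function(c_ff, c_total, c_ffla = NULL,
                        denominator = c("total", "tracee")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "total") {
    c_total
  } else {
    if (is.null(c_ffla)) {
      stop("c_ffla required for tracee-denominator TTR", call. = FALSE)
    }
    c_total - c_ff - c_ffla
  }
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-positive denominator; TTR set NA")
    denom[bad] <- NA_real_
  }
  c_ff / denom
}

#' Endogenous glucagon concentration
#'
#' The immunoassay total cannot distinguish tracer from endogenous glucagon;
#' the endogenous concentration is recovered by subtracting the
#' mass-spectrometric tracer concentrations from the total. Negative values
#' (possible from assay noise at low endogenous levels) are kept and
#' flagged.
#'
#' @param c_total,c_ff,c_ffla Concentration series, pg/ml.
#' @return A data.frame with columns `c_endo_pg_ml` and `below_zero`.
#' @export
endogenous_conc <- function(c_total, c_ff, c_ffla) {
  if (missing(c_total) || missing(c_ff) || missing(c_ffla)) {
    stop("c_total, c_ff and c_ffla are all required", call. = FALSE)
  }
  n <- length(c_total)
  if (length(c_ff) != n || length(c_ffla) != n) {
    stop("concentration series must have equal length", call. = FALSE)
  }
  endo <- c_total - c_ff - c_ffla
  data.frame(c_endo_pg_ml = endo, below_zero = endo < 0)
}

# Optional centered moving-average smoothing of a series before
# discretization; endpoints where the window does not fit keep raw values.
.smooth_series <- function(x, k) {
  if (k <= 0L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1),
                                 sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Glucagon rate of appearance (non-steady-state isotope dilution)
#'
#' Steele's non-steady-state single-pool estimator applied per
#' consecutive-sample interval:
#' \deqn{Ra = F_{FF}/\bar{TTR} - F_{FF} - F_{FFLA} -
#'       V_d \bar{C} (\Delta TTR/\Delta t)/\bar{TTR}}
#' with two-point interval means for TTR and total concentration, a
#' two-point finite difference for the TTR derivative, and infusion rates
#' evaluated at the interval midpoint. Results are assigned to interval
#' midpoints. Negative transients are reported with a flag, never clipped.
#'
#' @param protocol An [infusion_protocol()].
#' @param time Sampling times, min, strictly increasing.
#' @param ttr TTR series on the same grid (see [compute_ttr()]).
#' @param c_total Total glucagon, pg/ml, same grid.
#' @param vd_ml_kg Volume of distribution, ml/kg.
#' @param pool_fraction Multiplier on the effective pool volume used in the
#'   non-steady-state correction term (classical Steele analyses often use
#'   < 1; default 1 applies the estimator literally).
#' @param smooth_k Half-width (in samples) of an optional centered
#'   moving-average applied to the TTR series before differencing; 0 (the
#'   default) disables smoothing.
#' @return A data.frame with columns `t_mid_min`, `ra_pg_kg_min`, `flag`
#'   (`""`, `"negative"`, or `"undefined"`).
#' @export
rate_of_appearance <- function(protocol, time, ttr, c_total, vd_ml_kg,
                               pool_fraction = 1, smooth_k = 0L) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  if (vd_ml_kg <= 0) stop("vd_ml_kg must be positive", call. = FALSE)
  if (length(time) != length(ttr) || length(time) != length(c_total)) {
    stop("time, ttr and c_total must have equal length", call. = FALSE)
  }
  iv <- .steele_intervals_plain(time, .smooth_series(ttr, smooth_k), c_total)
  f_ff <- infusion_rate(protocol, iv$t_mid, "ff")
  f_ffla <- infusion_rate(protocol, iv$t_mid, "ffla")
  if (all(f_ff == 0) && protocol$bolus_pg == 0 &&
      any(is.finite(iv$ttr_bar) & iv$ttr_bar > 0)) {
    stop("nonzero TTR with zero FF tracer input is inconsistent",
         call. = FALSE)
  }
  undef <- !is.finite(iv$ttr_bar) | iv$ttr_bar <= 0
  ra <- ifelse(undef, NA_real_,
               f_ff / iv$ttr_bar - f_ff - f_ffla -
                 pool_fraction * vd_ml_kg * iv$c_bar * iv$dttr_dt / iv$ttr_bar)
  flag <- ifelse(undef, "undefined", ifelse(ra < 0, "negative", ""))
  data.frame(t_mid_min = iv$t_mid, ra_pg_kg_min = ra, flag = flag,
             stringsAsFactors = FALSE)
}

# two-point discretization without smoothing (the default path)
.steele_intervals_plain <- function(time, ttr, c_total) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  n <- length(time)
  i <- seq_len(n - 1L)
  list(t_mid = (time[i] + time[i + 1L]) / 2,
       ttr_bar = (ttr[i] + ttr[i + 1L]) / 2,
       dttr_dt = diff(ttr) / diff(time),
       c_bar = (c_total[i] + c_total[i + 1L]) / 2,
       dc_dt = diff(c_total) / diff(time))
}

#' Glucagon rate of disappearance
#'
#' Per interval: `Rd = Ra + F_FF + F_FFLA - Vd * (dC/dt)` with C the total
#' glucagon concentration, everything in the package's pg/kg/min unit
#' convention (Vd expressed per kg absorbs the body-weight division).
#'
#' @param ra A data.frame from [rate_of_appearance()] (same grid required).
#' @inheritParams rate_of_appearance
#' @return A data.frame with columns `t_mid_min`, `rd_pg_kg_min`, `flag`.
#' @export
rate_of_disappearance <- function(ra, protocol, time, c_total, vd_ml_kg) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  iv <- .steele_intervals_plain(time, rep(1, length(time)), c_total)
  if (nrow(ra) != length(iv$t_mid) ||
      max(abs(ra$t_mid_min - iv$t_mid)) > 1e-9) {
    stop("Ra grid does not match the concentration grid", call. = FALSE)
  }
  f_ff <- infusion_rate(protocol, iv$t_mid, "ff")
  f_ffla <- infusion_rate(protocol, iv$t_mid, "ffla")
  rd <- ra$ra_pg_kg_min + f_ff + f_ffla - vd_ml_kg * iv$dc_dt
  flag <- ifelse(!is.finite(rd), "undefined",
                 ifelse(rd < 0, "negative", ""))
  data.frame(t_mid_min = iv$t_mid, rd_pg_kg_min = rd, flag = flag,
             stringsAsFactors = FALSE)
}

#' Full two-tracer turnover analysis
#'
#' Convenience wrapper running the whole kinetics pipeline on a plasma time
#' series: TTR, endogenous concentration, volume of distribution (fitted
#' from post-bolus FF decay unless supplied), and interval Ra/Rd series.
#'
#' @param series A data.frame with columns `time_min`, `c_ff_pg_ml`,
#'   `c_ffla_pg_ml`, `c_total_pg_ml`.
#' @param protocol An [infusion_protocol()].
#' @param vd_ml_kg Volume of distribution; if NULL it is fitted from the
#'   post-bolus FF decay via [fit_vd()] using `decay_window`.
#' @param decay_window Length-2 numeric, time window (min) of the FF decay
#'   used for the Vd fit when `vd_ml_kg` is NULL.
#' @param ttr_denominator Passed to [compute_ttr()].
#' @param pool_fraction Passed to [rate_of_appearance()].
#' @return An object of class `"glucagon_kinetics"`: a list with `table`
#'   (midpoint grid with TTR means, Ra, Rd, flags), `series` (input plus
#'   `ttr` and `c_endo_pg_ml`), `vd_fit` (NULL if Vd supplied), `vd_ml_kg`,
#'   and `protocol`.
#' @export
glucagon_kinetics <- function(series, protocol, vd_ml_kg = NULL,
                              decay_window = NULL,
                              ttr_denominator = c("total", "tracee"),
                              pool_fraction = 1) {
  ttr_denominator <- match.arg(ttr_denominator)
  .require_columns(series, c("time_min", "c_ff_pg_ml", "c_ffla_pg_ml",
                             "c_total_pg_ml"))
  vd_fit <- NULL
  if (is.null(vd_ml_kg)) {
    if (protocol$bolus_pg <= 0) {
      stop("vd_ml_kg not supplied and no bolus to fit it from",
           call. = FALSE)
    }
    sel <- if (is.null(decay_window)) rep(TRUE, nrow(series)) else
      series$time_min >= decay_window[1L] & series$time_min <= decay_window[2L]
    vd_fit <- fit_vd(series$time_min[sel], series$c_ff_pg_ml[sel],
                     bolus_pg = protocol$bolus_pg, tbw_kg = protocol$tbw_kg)
    vd_ml_kg <- vd_fit$vd_ml_kg
  }
  ttr <- compute_ttr(series$c_ff_pg_ml, series$c_total_pg_ml,
                     series$c_ffla_pg_ml, denominator = ttr_denominator)
  endo <- endogenous_conc(series$c_total_pg_ml, series$c_ff_pg_ml,
                          series$c_ffla_pg_ml)
  ra <- rate_of_appearance(protocol, series$time_min, ttr,
                           series$c_total_pg_ml, vd_ml_kg, pool_fraction)
  rd <- rate_of_disappearance(ra, protocol, series$time_min,
                              series$c_total_pg_ml, vd_ml_kg)
  tab <- data.frame(t_mid_min = ra$t_mid_min,
                    ttr = (ttr[-length(ttr)] + ttr[-1L]) / 2,
                    ra_pg_kg_min = ra$ra_pg_kg_min,
                    rd_pg_kg_min = rd$rd_pg_kg_min,
                    flag = ifelse(ra$flag != "", ra$flag, rd$flag),
                    stringsAsFactors = FALSE)
  out <- list(table = tab,
              series = cbind(series, ttr = ttr,
                             c_endo_pg_ml = endo$c_endo_pg_ml),
              vd_fit = vd_fit, vd_ml_kg = vd_ml_kg, protocol = protocol,
              pool_fraction = pool_fraction,
              ttr_denominator = ttr_denominator)
  class(out) <- "glucagon_kinetics"
  out
}

#' @export
print.glucagon_kinetics <- function(x, ...) {
  cat("Two-tracer glucagon turnover analysis\n")
  cat(sprintf("  %d samples, %d intervals, t = %g-%g min\n",
              nrow(x$series), nrow(x$table), min(x$series$time_min),
              max(x$series$time_min)))
  cat(sprintf("  Vd = %.2f ml/kg (%s)\n", x$vd_ml_kg,
              if (is.null(x$vd_fit)) "supplied" else "fitted from bolus decay"))
  ok <- x$table$flag == ""
  cat(sprintf("  median Ra = %.2f, median Rd = %.2f pg/kg/min (%d/%d clean intervals)\n",
              stats::median(x$table$ra_pg_kg_min[ok]),
              stats::median(x$table$rd_pg_kg_min[ok]),
              sum(ok), nrow(x$table)))
  invisible(x)
}

#' @export
summary.glucagon_kinetics <- function(object, ...) {
  print(object)
  cat("\nInterval estimates (head):\n")
  print(utils::head(object$table, 8L), row.names = FALSE)
  if (!is.null(object$vd_fit)) {
    cat("\n")
    print(object$vd_fit)
  }
  invisible(object)
}

#' @export
plot.glucagon_kinetics <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ok <- x$table$flag != "undefined"
  graphics::plot(x$table$t_mid_min[ok], x$table$ra_pg_kg_min[ok],
                 type = "l", xlab = "Time (min)",
                 ylab = "Ra (pg/kg/min)", main = "Rate of appearance")
  graphics::plot(x$table$t_mid_min[ok], x$table$rd_pg_kg_min[ok],
                 type = "l", xlab = "Time (min)",
                 ylab = "Rd (pg/kg/min)", main = "Rate of disappearance")
  invisible(x)
}
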