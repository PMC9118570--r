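# One-compartment volume of distribution from tracer bolus decay.

#' Fit volume of distribution from mono-exponential bolus decay
#'
#' Fits the linear single-compartment model `C(t) = C0 * exp(-k * t)` to
#' post-bolus FF tracer concentrations by nonlinear least squares
#' (Levenberg-Marquardt, started from a log-linear regression) and reports
#' the apparent volume of distribution `Vd = (dose / C0) / TBW` in ml/kg
#' together with the elimination rate constant and fit diagnostics.
#'
#' @param time Sampling times since the bolus, min (>= 3 points).
#' @param conc Tracer concentration, pg/ml.
#' @param bolus_pg Bolus dose, pg.
#' @param tbw_kg Total body weight, kg.
#' @return An object of class `"vd_fit"` with components `c0_pg_ml`,
#'   `k_per_min` (elimination rate), `vd_ml_kg`, `half_life_min`,
#'   `se` (named standard errors for C0 and k, with the delta-method SE for
#'   Vd), `residual_sd`, and the underlying `nls` object.
#' @examples
#' t <- c(1, 2, 3, 5, 7, 10, 15)
#' fit_vd(t, 2500 * exp(-0.1 * t), bolus_pg = 7e6, tbw_kg = 70)
#' @export
fit_vd <- function(time, conc, bolus_pg, tbw_kg) {
  if (length(time) != length(conc)) {
    stop("time and conc must have equal length", call. = FALSE)
  }
  keep <- is.finite(time) & is.finite(conc)
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 3L) {
    stop("need at least 3 post-bolus points", call. = FALSE)
  }
  if (bolus_pg <= 0 || tbw_kg <= 0) {
    stop("bolus_pg and tbw_kg must be positive", call. = FALSE)
  }
  if (any(conc <= 0)) {
    stop("non-positive concentrations; cannot fit exponential decay",
         call. = FALSE)
  }
  start_fit <- stats::lm(log(conc) ~ time)
  k0 <- -unname(stats::coef(start_fit)[2L])
  if (!is.finite(k0) || k0 <= 0) {
    stop("concentrations do not decay; mono-exponential fit failed",
         call. = FALSE)
  }
  c00 <- exp(unname(stats::coef(start_fit)[1L]))
  fit <- minpack.lm::nlsLM(conc ~ c0 * exp(-k * time),
                           start = list(c0 = c00, k = k0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  if (est[["k"]] <= 0) {
    stop("fitted elimination rate is not positive; decay fit failed",
         call. = FALSE)
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  vd <- (bolus_pg / est[["c0"]]) / tbw_kg
  out <- list(
    c0_pg_ml = est[["c0"]],
    k_per_min = est[["k"]],
    vd_ml_kg = vd,
    half_life_min = log(2) / est[["k"]],
    se = c(c0 = unname(se[["c0"]]), k = unname(se[["k"]]),
           vd = vd * unname(se[["c0"]]) / est[["c0"]]),
    residual_sd = summary(fit)$sigma,
    bolus_pg = bolus_pg, tbw_kg = tbw_kg,
    n = length(time), fit = fit
  )
  class(out) <- "vd_fit"
  out
}

#' @export
print.vd_fit <- function(x, ...) {
  cat("One-compartment bolus-decay fit\n")
  cat(sprintf("  C0 = %.4g pg/ml (SE %.2g), k = %.4g /min (SE %.2g)\n",
              x$c0_pg_ml, x$se[["c0"]], x$k_per_min, x$se[["k"]]))
  cat(sprintf("  Vd = %.4g ml/kg (SE %.2g), half-life = %.3g min\n",
              x$vd_ml_kg, x$se[["vd"]], x$half_life_min))
  cat(sprintf("  residual SD %.3g pg/ml on %d points\n", x$residual_sd, x$n))
  invisible(x)
}

#' @export
coef.vd_fit <- function(object, ...) {
  c(c0_pg_ml = object$c0_pg_ml, k_per_min = object$k_per_min,
    vd_ml_kg = object$vd_ml_kg)
}

#' Predicted tracer concentration from a bolus-decay fit
#' @param object A `vd_fit`.
#' @param time Times (min) at which to predict; default the fitted times.
#' @param ... Unused.
#' @export
predict.vd_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) {
    return(stats::predict(object$fit))
  }
  object$c0_pg_ml * exp(-object$k_per_min * time)
}

#' @export
residuals.vd_fit <- function(object, ...) stats::residuals(object$fit)
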