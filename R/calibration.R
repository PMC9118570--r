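# Calibration-curve quantitation: area ratios, curve fitting, inverse
# prediction, infusate dilution bookkeeping.

#' Analyte / internal-standard peak-area ratio
#'
#' Quantitation is performed on the ratio of the analyte peak area to the
#' co-analyzed internal-standard (F22 glucagon) peak area, which normalizes
#' recovery and ionization between samples. A non-positive IS area signals a
#' failed enrichment and is an error, never a silent zero.
#'
#' @param analyte_area,is_area Peak areas (arbitrary units). Vectorized.
#' @return Dimensionless area ratio.
#' @export
area_ratio <- function(analyte_area, is_area) {
  if (any(!is.finite(is_area)) || any(is_area <= 0)) {
    stop("internal-standard area must be positive (failed enrichment?)",
         call. = FALSE)
  }
  analyte_area / is_area
}

#' Fit an area-ratio calibration curve
#'
#' Least-squares line of mean area ratio on nominal concentration over the
#' calibration levels. Replicates are averaged per level before fitting; the
#' Pearson correlation coefficient r is reported on the same level means.
#' Optional `1/x` or `1/x^2` weighting (weights on nominal concentration) is
#' available for heteroscedastic data; the default is unweighted, matching
#' plain linear-regression practice.
#'
#' @param standards A data.frame with columns `nominal_pg_ml`,
#'   `analyte_area`, `is_area` (one row per replicate) and optionally
#'   `species`. Rows with missing IS area (blank / plasma-only controls) are
#'   excluded from the fit.
#' @param weighting `"none"`, `"1/x"` or `"1/x2"`.
#' @return An object of class `"calibration_curve"` with components `slope`,
#'   `intercept`, `r`, `weighting`, `species`, `levels` (per-level mean
#'   ratios), `lod`, `loq` (NA until set), and the underlying `lm` fit.
#' @seealso [inverse_predict()], [evaluate_lod()], [evaluate_loq()]
#' @examples
#' d <- data.frame(nominal_pg_ml = rep(c(5, 10, 20, 40), each = 2))
#' d$is_area <- 1e5
#' d$analyte_area <- 0.02 * d$nominal_pg_ml * d$is_area
#' fit_calibration(d)
#' @export
fit_calibration <- function(standards, weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  .require_columns(standards, c("nominal_pg_ml", "analyte_area", "is_area"))
  standards <- standards[!is.na(standards$is_area), , drop = FALSE]
  if (any(standards$nominal_pg_ml <= 0)) {
    stop("nominal concentrations must be positive", call. = FALSE)
  }
  ratio <- area_ratio(standards$analyte_area, standards$is_area)
  conc <- standards$nominal_pg_ml
  levels_df <- stats::aggregate(ratio, by = list(nominal_pg_ml = conc),
                                FUN = mean)
  names(levels_df)[2L] <- "mean_ratio"
  if (nrow(levels_df) < 3L) {
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  }
  if (stats::var(levels_df$nominal_pg_ml) == 0) {
    stop("zero variance in nominal concentrations", call. = FALSE)
  }
  w <- switch(weighting,
              none = NULL,
              `1/x` = 1 / levels_df$nominal_pg_ml,
              `1/x2` = 1 / levels_df$nominal_pg_ml^2)
  fit <- stats::lm(mean_ratio ~ nominal_pg_ml, data = levels_df, weights = w)
  species <- if ("species" %in% names(standards)) {
    unique(as.character(standards$species))[1L]
  } else NA_character_
  structure(list(
    species = species,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = stats::cor(levels_df$nominal_pg_ml, levels_df$mean_ratio),
    weighting = weighting,
    levels = levels_df,
    lod_pg_ml = NA_real_,
    loq_pg_ml = NA_real_,
    fit = fit,
    call = match.call()
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, digits = 4, ...) {
  cat("Area-ratio calibration curve",
      if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  ratio = %.6g + %.6g * conc [pg/ml]   (weighting: %s)\n",
              x$intercept, x$slope, x$weighting))
  cat(sprintf("  r = %.4f over %d levels (%.3g-%.3g pg/ml)\n", x$r,
              nrow(x$levels), min(x$levels$nominal_pg_ml),
              max(x$levels$nominal_pg_ml)))
  if (!is.na(x$lod_pg_ml)) cat(sprintf("  LOD = %.3g pg/ml\n", x$lod_pg_ml))
  if (!is.na(x$loq_pg_ml)) cat(sprintf("  LOQ = %.3g pg/ml\n", x$loq_pg_ml))
  invisible(x)
}

#' @export
summary.calibration_curve <- function(object, ...) {
  print(object)
  cat("\nPer-level mean ratios:\n")
  lv <- object$levels
  lv$back_calc_pg_ml <- inverse_predict(object, lv$mean_ratio)$conc_pg_ml
  print(lv, row.names = FALSE)
  invisible(object)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted area ratio at given concentrations
#' @param object A `calibration_curve`.
#' @param newdata Optional data.frame with column `nominal_pg_ml` (or a
#'   numeric vector of concentrations); default the fitted levels.
#' @param ... Unused.
#' @export
predict.calibration_curve <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$levels$nominal_pg_ml
  } else if (is.numeric(newdata)) newdata else newdata$nominal_pg_ml
  object$intercept + object$slope * conc
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$levels$nominal_pg_ml, x$levels$mean_ratio,
                 xlab = "Nominal concentration (pg/ml)",
                 ylab = "Mean area ratio (analyte / IS)",
                 main = if (!is.na(x$species)) {
                   paste("Calibration:", x$species)
                 } else "Calibration curve", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Back-calculate concentration from an area ratio
#'
#' Inverse prediction through a fitted calibration curve:
#' `(ratio - intercept) / slope`. Negative back-calculated concentrations
#' (possible for noisy measurements near the blank) are returned as-is with
#' a `below_zero` flag so that downstream QC statistics remain unbiased.
#'
#' @param curve A [fit_calibration()] object.
#' @param ratio Numeric vector of area ratios.
#' @return A data.frame with columns `ratio`, `conc_pg_ml`, `below_zero`.
#' @export
inverse_predict <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0) {
    stop("calibration slope is zero; cannot invert", call. = FALSE)
  }
  conc <- (ratio - curve$intercept) / curve$slope
  data.frame(ratio = ratio, conc_pg_ml = conc, below_zero = conc < 0)
}

#' Expected infusate concentration after dilution
#'
#' Converts a stock concentration to the expected concentration of a diluted
#' infusate sample, normalizing micrograms/ml to pg/ml.
#'
#' @param stock Stock concentration.
#' @param dilution_factor Fold dilution (>= 1); e.g. 100 for a 1/100
#'   dilution.
#' @param stock_unit `"ug_ml"` (default) or `"pg_ml"`.
#' @return Expected concentration in pg/ml.
#' @examples
#' expected_infusate_conc(0.0465, 100)  # 465 pg/ml
#' @export
expected_infusate_conc <- function(stock, dilution_factor,
                                   stock_unit = c("ug_ml", "pg_ml")) {
  stock_unit <- match.arg(stock_unit)
  if (any(stock <= 0) || any(dilution_factor < 1)) {
    stop("stock must be positive and dilution factor >= 1", call. = FALSE)
  }
  pg <- if (stock_unit == "ug_ml") stock * 1e6 else stock
  pg / dilution_factor
}
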