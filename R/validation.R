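# Bioanalytical validation: LOD, LOQ, and QC precision statistics.

#' Limit-of-detection decision per calibration level
#'
#' A level passes the detection criteria when every replicate's
#' signal-to-noise ratio is at least `snr_min` AND the mean level response
#' exceeds the blank mean by at least `k_sd` blank standard deviations. The
#' LOD is the lowest passing concentration. S/N values come from upstream
#' peak integration and are accepted as inputs.
#'
#' @param levels A data.frame with columns `nominal_pg_ml`, `response`
#'   (area or area ratio, one row per replicate) and `snr`.
#' @param blank_responses Numeric vector of blank (plasma-only) responses;
#'   at least 2 to estimate the blank SD.
#' @param snr_min Minimum acceptable S/N (default 3).
#' @param k_sd Number of blank SDs the level mean must exceed the blank mean
#'   by (default 3).
#' @return A list with `table` (per-level decisions) and `lod_pg_ml`
#'   (NA if no level passes).
#' @export
evaluate_lod <- function(levels, blank_responses, snr_min = 3, k_sd = 3) {
  .require_columns(levels, c("nominal_pg_ml", "response", "snr"))
  if (length(blank_responses) < 2L) {
    stop("need at least 2 blank replicates to estimate blank SD",
         call. = FALSE)
  }
  blank_mean <- mean(blank_responses)
  blank_sd <- stats::sd(blank_responses)
  conc <- sort(unique(levels$nominal_pg_ml))
  tab <- do.call(rbind, lapply(conc, function(cc) {
    sub <- levels[levels$nominal_pg_ml == cc, , drop = FALSE]
    data.frame(nominal_pg_ml = cc,
               mean_response = mean(sub$response),
               min_snr = min(sub$snr),
               snr_pass = min(sub$snr) >= snr_min,
               blank_pass = mean(sub$response) >= blank_mean + k_sd * blank_sd)
  }))
  tab$pass <- tab$snr_pass & tab$blank_pass
  lod <- if (any(tab$pass)) min(tab$nominal_pg_ml[tab$pass]) else NA_real_
  list(table = tab, lod_pg_ml = lod,
       blank_mean = blank_mean, blank_sd = blank_sd)
}

#' Limit of quantitation from replicate precision and accuracy
#'
#' The LOQ is the lowest concentration level whose replicate measurements
#' meet both the precision criterion (CV <= `cv_max`, default 25%) and the
#' accuracy criterion (|mean - nominal| / nominal <= `re_max`, default 25%).
#'
#' @param measurements A data.frame with columns `nominal_pg_ml` and
#'   `measured_pg_ml` (back-calculated concentrations, >= 3 replicates per
#'   level).
#' @param cv_max,re_max Acceptance thresholds in percent.
#' @return A list with `table` (per-level CV%, RE%, pass) and `loq_pg_ml`
#'   (NA with all-fail diagnostics if no level passes).
#' @export
evaluate_loq <- function(measurements, cv_max = 25, re_max = 25) {
  .require_columns(measurements, c("nominal_pg_ml", "measured_pg_ml"))
  conc <- sort(unique(measurements$nominal_pg_ml))
  tab <- do.call(rbind, lapply(conc, function(cc) {
    x <- measurements$measured_pg_ml[measurements$nominal_pg_ml == cc]
    if (length(x) < 3L) {
      stop("need >= 3 replicates per level (", cc, " pg/ml has ",
           length(x), ")", call. = FALSE)
    }
    cv <- 100 * stats::sd(x) / mean(x)
    re <- 100 * abs(mean(x) - cc) / cc
    data.frame(nominal_pg_ml = cc, n = length(x), cv_pct = cv, re_pct = re)
  }))
  tab$pass <- tab$cv_pct <= cv_max & tab$re_pct <= re_max
  loq <- if (any(tab$pass)) min(tab$nominal_pg_ml[tab$pass]) else NA_real_
  list(table = tab, loq_pg_ml = loq)
}

#' Intra- and inter-day QC precision
#'
#' Intra-day CV is the pooled within-day CV (root-mean-square of the per-day
#' CVs); inter-day CV is, by default, the total CV of all measurements
#' across days. A pooled-ANOVA between-day estimator is available with
#' `inter_method = "anova"`, which extracts the between-day variance
#' component from a one-way random-effects decomposition.
#'
#' @param measurements A data.frame with columns `day`, `measured_pg_ml`,
#'   and optionally `nominal_pg_ml` and `species`.
#' @param inter_method `"total"` (default) or `"anova"`.
#' @return A one-row data.frame of class `"qc_precision"` with columns
#'   `species`, `nominal_pg_ml`, `n_days`, `n_total`, `intra_day_cv_pct`,
#'   `inter_day_cv_pct`, `re_pct` (NA if no nominal given).
#' @examples
#' d <- data.frame(day = rep(1:3, each = 3),
#'                 measured_pg_ml = c(13, 13.5, 13.2, 12.8, 13.1, 13.4,
#'                                    13.6, 13.0, 12.9))
#' qc_precision(d)
#' @export
qc_precision <- function(measurements, inter_method = c("total", "anova")) {
  inter_method <- match.arg(inter_method)
  .require_columns(measurements, c("day", "measured_pg_ml"))
  x <- measurements$measured_pg_ml
  day <- factor(measurements$day)
  n_per_day <- table(day)
  if (any(n_per_day < 2L)) {
    stop("need >= 2 replicates per day for intra-day CV", call. = FALSE)
  }
  day_cv <- tapply(x, day, function(v) stats::sd(v) / mean(v))
  intra <- 100 * sqrt(mean(day_cv^2))
  if (nlevels(day) < 2L) {
    stop("need >= 2 days for inter-day CV", call. = FALSE)
  }
  inter <- if (inter_method == "total") {
    100 * stats::sd(x) / mean(x)
  } else {
    aov_fit <- stats::aov(x ~ day)
    ms <- summary(aov_fit)[[1L]][["Mean Sq"]]
    n0 <- mean(n_per_day)  # exact for balanced designs
    var_between <- max((ms[1L] - ms[2L]) / n0, 0)
    100 * sqrt(var_between + ms[2L]) / mean(x)
  }
  nominal <- if ("nominal_pg_ml" %in% names(measurements)) {
    unique(measurements$nominal_pg_ml)[1L]
  } else NA_real_
  species <- if ("species" %in% names(measurements)) {
    as.character(unique(measurements$species))[1L]
  } else NA_character_
  out <- data.frame(species = species, nominal_pg_ml = nominal,
                    n_days = nlevels(day), n_total = length(x),
                    intra_day_cv_pct = intra, inter_day_cv_pct = inter,
                    re_pct = if (is.na(nominal)) NA_real_ else
                      100 * abs(mean(x) - nominal) / nominal)
  class(out) <- c("qc_precision", class(out))
  out
}
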