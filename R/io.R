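# File I/O and schema checks shared across the pipeline. All CSVs are
# comma-separated, UTF-8, "." decimal, with a required header row; units are
# encoded in column names (e.g. c_ff_pg_ml) to prevent silent unit errors.

.require_columns <- function(df, cols, where = "input") {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s) in ", where, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read / write a plasma time-series CSV
#'
#' Schema: `time_min, c_ff_pg_ml, c_ffla_pg_ml, c_total_pg_ml` (extra
#' columns are preserved).
#'
#' @param path CSV path.
#' @param series A plasma time-series data.frame.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
read_plasma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_min", "c_ff_pg_ml", "c_ffla_pg_ml",
                         "c_total_pg_ml"), path)
  if (is.unsorted(df$time_min, strictly = TRUE)) {
    stop("time_min must be strictly increasing in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_plasma_csv
#' @export
write_plasma_csv <- function(series, path) {
  .require_columns(series, c("time_min", "c_ff_pg_ml", "c_ffla_pg_ml",
                             "c_total_pg_ml"))
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration / QC peak-area CSV
#'
#' Schema: `species, level_id, nominal_pg_ml, day, replicate, analyte_area,
#' is_area` with optional `snr`.
#'
#' @param path CSV path.
#' @return The validated data.frame.
#' @export
read_area_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("species", "level_id", "nominal_pg_ml", "day",
                         "replicate", "analyte_area", "is_area"), path)
  df
}

#' Read / write an infusion protocol as JSON
#'
#' JSON fields: `tbw_kg`, `bolus_pg`, and `f_ff` / `f_ffla` arrays of
#' `{t_start, t_end, rate}` segments.
#'
#' @param path JSON path.
#' @param protocol An [infusion_protocol()].
#' @return The protocol object (read) or `path` invisibly (write).
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$tbw_kg)) {
    stop("missing required field in ", path, ": tbw_kg", call. = FALSE)
  }
  as_seg <- function(s) if (is.null(s) || length(s) == 0L) NULL else
    as.data.frame(s)
  infusion_protocol(tbw_kg = x$tbw_kg,
                    bolus_pg = if (is.null(x$bolus_pg)) 0 else x$bolus_pg,
                    f_ff = as_seg(x$f_ff), f_ffla = as_seg(x$f_ffla))
}

#' @rdname read_protocol_json
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Build peptide species from a configuration list
#'
#' Each species entry has a `sequence` and a `labels` character vector of
#' `"position:element:count"` triples (e.g. `"6:C:9"` for 13C9 at residue
#' 6). Named entries matching the built-ins may omit everything to get the
#' built-in definition.
#'
#' @param config A named list: species name -> list(sequence, labels) or an
#'   empty list for a built-in species.
#' @return Named list of [peptide_species()] objects.
#' @export
species_from_config <- function(config) {
  lapply(stats::setNames(nm = names(config)), function(nm) {
    entry <- config[[nm]]
    if (is.null(entry$sequence)) {
      return(glucagon_species(nm)[[1L]])
    }
    labels <- list()
    for (triple in entry$labels %||% character(0)) {
      parts <- strsplit(triple, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 3L) {
        stop("bad label triple (want position:element:count): ", triple,
             call. = FALSE)
      }
      pos <- parts[1L]
      labels[[pos]] <- c(labels[[pos]],
                         list(isotope_label(parts[2L],
                                            as.integer(parts[3L]))))
    }
    peptide_species(nm, entry$sequence, labels)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline run configuration
#'
#' A single human-editable YAML file with optional sections `species`,
#' `layout` (arguments of [transition_layout()]), `calibration`
#' (`weighting`), `kinetics` (`ttr_denominator`, `pool_fraction`,
#' `smooth_k`, `vd_ml_kg`, `decay_window`), `simulation` (arguments of
#' [simulation_truth()] with `ra_endo` as
#' `list(basal, peak, t_peak, decay)`) and `seed`. Unknown top-level keys
#' are rejected.
#'
#' @param path YAML path.
#' @return A named list of validated sections with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("species", "layout", "calibration", "kinetics", "simulation",
             "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$calibration$weighting <- cfg$calibration$weighting %||% "none"
  cfg
}

#' Pipeline commands
#'
#' Thin composition of the package's stages, each writing its outputs under
#' `out_dir` and returning the result object invisibly. These are the
#' programmatic equivalents of the shell subcommands in
#' `inst/cli/glucatrace.R`.
#'
#' `run_transitions` writes the SIM/PRM transition list;
#' `run_calibrate` fits the calibration curve and QC statistics from a
#' peak-area CSV; `run_kinetics` runs the turnover analysis on a plasma CSV
#' plus protocol JSON; `run_simulate` generates a synthetic study;
#' `run_recover` simulates, analyzes, and compares estimates with truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param species Named list of [peptide_species()] (default the four
#'   built-ins).
#' @param layout A [transition_layout()].
#' @param areas_csv Peak-area CSV path (see [read_area_csv()]).
#' @param weighting Calibration weighting scheme.
#' @param series_csv Plasma time-series CSV path.
#' @param protocol_json Infusion-protocol JSON path.
#' @param truth A [simulation_truth()].
#' @param ... Passed through to the underlying stage.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_transitions <- function(out_dir, species = glucagon_species(),
                            layout = transition_layout()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tt <- transition_table(species, layout)
  write_transition_csv(tt, file.path(out_dir, "transitions.csv"))
  message(sprintf("wrote %d transitions for %d species", nrow(tt),
                  length(species)))
  invisible(tt)
}

#' @rdname pipeline
#' @export
run_calibrate <- function(areas_csv, out_dir, weighting = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  areas <- read_area_csv(areas_csv)
  curve <- fit_calibration(areas, weighting = weighting)
  meas <- inverse_predict(curve, area_ratio(areas$analyte_area,
                                            areas$is_area))
  loq <- evaluate_loq(data.frame(nominal_pg_ml = areas$nominal_pg_ml,
                                 measured_pg_ml = meas$conc_pg_ml))
  curve$loq_pg_ml <- loq$loq_pg_ml
  qc <- do.call(rbind, lapply(split(
    data.frame(day = areas$day, measured_pg_ml = meas$conc_pg_ml,
               nominal_pg_ml = areas$nominal_pg_ml, species = areas$species),
    areas$nominal_pg_ml), function(d) {
      if (length(unique(d$day)) >= 2L) qc_precision(d) else NULL
    }))
  jsonlite::write_json(
    list(species = curve$species, slope = curve$slope,
         intercept = curve$intercept, r = curve$r,
         weighting = curve$weighting, loq_pg_ml = curve$loq_pg_ml),
    file.path(out_dir, "curve.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(loq$table, file.path(out_dir, "loq.csv"),
                   row.names = FALSE)
  if (!is.null(qc)) {
    utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  }
  message(sprintf("calibration r = %.4f, LOQ = %s pg/ml", curve$r,
                  format(curve$loq_pg_ml)))
  invisible(list(curve = curve, loq = loq, qc = qc))
}

#' @rdname pipeline
#' @export
run_kinetics <- function(series_csv, protocol_json, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- read_plasma_csv(series_csv)
  protocol <- read_protocol_json(protocol_json)
  res <- glucagon_kinetics(series, protocol, ...)
  utils::write.csv(res$table, file.path(out_dir, "kinetics.csv"),
                   row.names = FALSE)
  fit_report <- list(vd_ml_kg = res$vd_ml_kg)
  if (!is.null(res$vd_fit)) {
    fit_report <- c(fit_report,
                    list(k_per_min = res$vd_fit$k_per_min,
                         c0_pg_ml = res$vd_fit$c0_pg_ml,
                         se = as.list(res$vd_fit$se),
                         residual_sd = res$vd_fit$residual_sd))
  }
  jsonlite::write_json(fit_report, file.path(out_dir, "vd_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("kinetics: %d intervals, Vd = %.2f ml/kg",
                  nrow(res$table), res$vd_ml_kg))
  invisible(res)
}

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, truth = simulation_truth(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_kinetics(truth, ...)
  write_plasma_csv(ds$noisy, file.path(out_dir, "plasma_noisy.csv"))
  write_plasma_csv(ds$noiseless, file.path(out_dir, "plasma_noiseless.csv"))
  write_protocol_json(truth$protocol, file.path(out_dir, "protocol.json"))
  jsonlite::write_json(
    list(vd_ml_kg = truth$vd_ml_kg, k_per_min = truth$k_per_min,
         seed = truth$seed, cv = as.list(truth$cv),
         sample_times_min = truth$sample_times_min,
         ra_endo_at_samples = truth$ra_endo(truth$sample_times_min)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  message(sprintf("simulated %d samples (seed %d)", nrow(ds$noisy),
                  truth$seed))
  invisible(ds)
}

#' @rdname pipeline
#' @export
run_recover <- function(out_dir, truth = simulation_truth(), ...) {
  ds <- run_simulate(out_dir, truth, ...)
  res <- glucagon_kinetics(ds$noisy, truth$protocol,
                           vd_ml_kg = truth$vd_ml_kg)
  t_mid <- res$table$t_mid_min
  ra_true <- (truth$ra_endo(ds$noisy$time_min[-nrow(ds$noisy)]) +
                truth$ra_endo(ds$noisy$time_min[-1L])) / 2
  cmp <- data.frame(t_mid_min = t_mid, ra_est = res$table$ra_pg_kg_min,
                    ra_true = ra_true)
  cmp$rel_err <- (cmp$ra_est - cmp$ra_true) / cmp$ra_true
  utils::write.csv(cmp, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  message(sprintf("Ra recovery: mean |relative error| = %.3f",
                  mean(abs(cmp$rel_err), na.rm = TRUE)))
  invisible(list(dataset = ds, kinetics = res, comparison = cmp))
}
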