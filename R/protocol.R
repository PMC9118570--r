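# Infusion protocol: bolus + piecewise-constant tracer infusions.

#' Define a two-tracer infusion protocol
#'
#' Holds the dosing that produced a plasma time series: an optional FF
#' glucagon priming bolus, piecewise-constant infusion schedules for the FF
#' and FFLA tracers, and the subject's body weight. Infusion rates are in
#' pg per kg body weight per minute; segments are matrices/data.frames with
#' columns `t_start`, `t_end`, `rate` (half-open intervals
#' `[t_start, t_end)`); the rate is 0 outside all segments.
#'
#' @param tbw_kg Total body weight, kg.
#' @param bolus_pg FF glucagon bolus dose, pg (0 for none).
#' @param f_ff,f_ffla Infusion schedules, each a data.frame with columns
#'   `t_start`, `t_end`, `rate` (pg/kg/min), or NULL for no infusion.
#' @return An object of class `"infusion_protocol"`.
#' @examples
#' infusion_protocol(tbw_kg = 70, bolus_pg = 1.4e5,
#'                   f_ffla = data.frame(t_start = 0, t_end = 350, rate = 8))
#' @export
infusion_protocol <- function(tbw_kg, bolus_pg = 0, f_ff = NULL,
                              f_ffla = NULL) {
  if (length(tbw_kg) != 1L || !is.finite(tbw_kg) || tbw_kg <= 0) {
    stop("tbw_kg must be a positive scalar", call. = FALSE)
  }
  if (bolus_pg < 0) stop("bolus_pg must be >= 0", call. = FALSE)
  check_segments <- function(seg, what) {
    if (is.null(seg)) return(NULL)
    seg <- as.data.frame(seg)
    .require_columns(seg, c("t_start", "t_end", "rate"))
    if (any(seg$rate < 0)) stop(what, " rates must be >= 0", call. = FALSE)
    if (any(seg$t_end <= seg$t_start)) {
      stop(what, " segments must have t_end > t_start", call. = FALSE)
    }
    seg
  }
  structure(list(tbw_kg = tbw_kg, bolus_pg = bolus_pg,
                 f_ff = check_segments(f_ff, "f_ff"),
                 f_ffla = check_segments(f_ffla, "f_ffla")),
            class = "infusion_protocol")
}

#' Infusion rate at given times
#'
#' @param protocol An [infusion_protocol()].
#' @param time Numeric vector of times, min.
#' @param tracer `"ff"` or `"ffla"`.
#' @return Rate in pg/kg/min at each time (0 outside all segments).
#' @export
infusion_rate <- function(protocol, time, tracer = c("ff", "ffla")) {
  tracer <- match.arg(tracer)
  seg <- if (tracer == "ff") protocol$f_ff else protocol$f_ffla
  rate <- numeric(length(time))
  if (is.null(seg)) return(rate)
  for (i in seq_len(nrow(seg))) {
    inside <- time >= seg$t_start[i] & time < seg$t_end[i]
    rate[inside] <- rate[inside] + seg$rate[i]
  }
  rate
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat("Infusion protocol\n")
  cat(sprintf("  body weight: %.1f kg\n", x$tbw_kg))
  cat(sprintf("  FF bolus: %.3g pg\n", x$bolus_pg))
  show_seg <- function(seg, name) {
    if (is.null(seg)) {
      cat(sprintf("  %s infusion: none\n", name))
    } else {
      for (i in seq_len(nrow(seg))) {
        cat(sprintf("  %s infusion: %.3g pg/kg/min over [%g, %g) min\n",
                    name, seg$rate[i], seg$t_start[i], seg$t_end[i]))
      }
    }
  }
  show_seg(x$f_ff, "FF")
  show_seg(x$f_ffla, "FFLA")
  invisible(x)
}
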