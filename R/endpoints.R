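#' Windowed physiological endpoints
#'
#' These functions compute the standard UIH endpoints from core-temperature,
#' BAT-temperature and calorimetry traces. All windows are half-open
#' `[start, end)` in seconds and are specified *relative to the ultrasound
#' onset*; the published window conventions are provided as defaults through
#' [endpoint_config()]:
#'
#' * `t_bat`: baseline = the 15 min before onset, search = the 7-12 min
#'   interval after onset.
#' * `t_core` (and `vo2`, which uses the same rule): baseline = the 5-min
#'   window ending 1 min before onset, search = the 30 min after onset.
#' * `rq`: baseline = the 28-min window ending 2 min before onset, search =
#'   the 45-55 min interval after onset.
#'
#' @param baseline_window c(start, end) s relative to onset (both usually
#'   negative)
#' @param search_window c(start, end) s relative to onset
#' @param aggregation `"min"` for dips, `"max"` for rises
#' @return list of class `endpoint_config`
#' @export
#' @examples
#' endpoint_config("t_core")
endpoint_config <- function(endpoint = c("t_bat", "t_core", "vo2", "rq"),
                            baseline_window = NULL, search_window = NULL,
                            aggregation = "min") {
  endpoint <- match.arg(endpoint)
  defaults <- list(
    t_bat = list(baseline = c(-900, 0), search = c(420, 720)),
    t_core = list(baseline = c(-360, -60), search = c(0, 1800)),
    vo2 = list(baseline = c(-360, -60), search = c(0, 1800)),
    rq = list(baseline = c(-1800, -120), search = c(2700, 3300))
  )[[endpoint]]
  cfg <- list(
    endpoint = endpoint,
    baseline_window = baseline_window %||% defaults$baseline,
    search_window = search_window %||% defaults$search,
    aggregation = match.arg(aggregation, c("min", "max"))
  )
  assert_window(cfg$baseline_window, "baseline_window")
  assert_window(cfg$search_window, "search_window")
  if (cfg$baseline_window[2] > 0) {
    stop("baseline window must end at or before the stimulus onset",
         call. = FALSE)
  }
  structure(cfg, class = "endpoint_config")
}

#' @rdname endpoint_config
#' @param endpoint which endpoint's window convention to use
#' @export
endpoint_windows <- function(endpoint) {
  cfg <- endpoint_config(endpoint)
  tibble::tibble(endpoint = endpoint,
                 baseline_start_s = cfg$baseline_window[1],
                 baseline_end_s = cfg$baseline_window[2],
                 search_start_s = cfg$search_window[1],
                 search_end_s = cfg$search_window[2])
}

#' Baseline mean of a trace over an absolute window
#'
#' Arithmetic mean of the samples with `time_s` in `[window[1], window[2])`.
#'
#' @param trace data frame with `time_s`, `value`
#' @param window c(start, end), absolute seconds
#' @return mean value
#' @export
baseline_mean <- function(trace, window) {
  trace <- as_trace(trace)
  assert_window(window)
  sel <- in_window(trace$time_s, window)
  if (!any(sel)) stop("no baseline samples", call. = FALSE)
  mean(trace$value[sel])
}

#' Maximum windowed change relative to baseline
#'
#' The workhorse behind max dT_core, max dT_BAT, max dVO2 and max dRQ: the
#' extremum of the trace inside the search window minus the baseline mean.
#' With `aggregation = "min"` a dip yields a negative value.
#'
#' @param trace data frame with `time_s`, `value`
#' @param cfg an [endpoint_config()]
#' @param us_onset ultrasound onset time, absolute seconds
#' @return the signed change (same unit as the trace)
#' @export
#' @examples
#' tr <- new_trace(seq(-400, 1800, 20), c(rep(37, 20), 37 - 3 *
#'   exp(-(seq(-20, 1800, 20) - 600)^2 / 2e5)), "degC")
#' max_delta(tr, endpoint_config("t_core"), us_onset = 0)
max_delta <- function(trace, cfg = endpoint_config("t_core"), us_onset = 0) {
  trace <- as_trace(trace)
  stopifnot(inherits(cfg, "endpoint_config"))
  base <- baseline_mean(trace, us_onset + cfg$baseline_window)
  sel <- in_window(trace$time_s, us_onset + cfg$search_window)
  vals <- trace$value[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no samples in search window", call. = FALSE)
  agg <- if (cfg$aggregation == "min") min(vals) else max(vals)
  agg - base
}

#' Respiratory quotient trace
#'
#' Pointwise VCO2 / VO2 after aligning the two traces by nearest timestamp
#' (within `tolerance_s`). RQ is `NaN` wherever VO2 <= 0; time points in
#' VCO2 with no VO2 sample within tolerance are dropped.
#'
#' @param vco2,vo2 traces (data frames with `time_s`, `value`)
#' @param tolerance_s maximum timestamp mismatch for pairing, s
#' @return an RQ trace (unit `"ratio"`)
#' @export
rq_trace <- function(vco2, vo2, tolerance_s = 30) {
  vco2 <- as_trace(vco2); vo2 <- as_trace(vo2)
  if (min(vco2$time_s) > max(vo2$time_s) + tolerance_s ||
      max(vco2$time_s) < min(vo2$time_s) - tolerance_s) {
    stop("vco2 and vo2 time ranges do not overlap", call. = FALSE)
  }
  idx <- vapply(vco2$time_s, function(t) which.min(abs(vo2$time_s - t)),
                integer(1))
  keep <- abs(vo2$time_s[idx] - vco2$time_s) <= tolerance_s
  num <- vco2$value[keep]
  den <- vo2$value[idx[keep]]
  rq <- ifelse(den > 0, num / den, NaN)
  new_trace(vco2$time_s[keep], rq, "ratio")
}

#' @rdname max_delta
#' @param rq an RQ trace, e.g. from [rq_trace()]
#' @export
max_delta_rq <- function(rq, us_onset = 0) {
  max_delta(rq, endpoint_config("rq"), us_onset)
}

#' Onset time of the hypothermic/hypometabolic response
#'
#' First post-onset sample whose value falls below baseline mean minus two
#' baseline sample standard deviations. Returns `NA` when the trace never
#' crosses the threshold.
#'
#' @param trace data frame with `time_s`, `value`
#' @param us_onset ultrasound onset, absolute s
#' @param baseline_window c(start, end) s relative to onset
#' @return crossing time (absolute s) or `NA`
#' @export
uih_onset <- function(trace, us_onset = 0, baseline_window = c(-360, -60)) {
  trace <- as_trace(trace)
  assert_window(baseline_window, "baseline_window")
  sel <- in_window(trace$time_s, us_onset + baseline_window)
  if (sum(sel) < 2) stop("need >= 2 baseline samples", call. = FALSE)
  thr <- mean(trace$value[sel]) - 2 * sd(trace$value[sel])
  post <- trace$time_s >= us_onset & trace$value < thr
  if (!any(post)) return(NA_real_)
  trace$time_s[which(post)[1]]
}

#' End time of the UIH bout
#'
#' Recovery time of the bout: the trace first drops below `threshold`
#' (34 degC by convention) at or after `after`, and the end is the first
#' subsequent time it has returned to `threshold` or above. Returns `NA`
#' when the trace never drops below threshold (no bout) or never recovers
#' within the record.
#'
#' @param t_core core temperature trace
#' @param after time from which to search, absolute s
#' @param threshold recovery temperature, degC
#' @return recovery time (absolute s) or `NA`
#' @export
uih_end <- function(t_core, after = 0, threshold = 34) {
  t_core <- as_trace(t_core)
  if (max(t_core$time_s) < after) {
    stop("trace does not extend past `after`", call. = FALSE)
  }
  from <- t_core$time_s >= after
  below <- from & t_core$value < threshold
  if (!any(below)) return(NA_real_)
  first_below <- which(below)[1]
  rec <- t_core$value >= threshold &
    seq_along(t_core$value) > first_below
  if (!any(rec)) return(NA_real_)
  t_core$time_s[which(rec)[1]]
}

#' Duration of the UIH bout
#'
#' @param onset_s,end_s bout onset and end, absolute s (`NA` propagates)
#' @return duration in minutes, or `NA`
#' @export
uih_duration <- function(onset_s, end_s) {
  if (is.na(onset_s) || is.na(end_s)) return(NA_real_)
  (end_s - onset_s) / 60
}

#' Endpoint report for a full physiology recording
#'
#' Convenience wrapper computing max dT_core, max dVO2, max dRQ, bout onset,
#' end and duration from a [simulate_plant()] result or any tibble with the
#' same columns.
#'
#' @param sim tibble with `time_s`, `t_core`, `vo2`, `vco2`
#' @param us_onset ultrasound onset, absolute s
#' @return tidy tibble with one row per endpoint (`endpoint`, `value`, `unit`)
#' @export
endpoint_report <- function(sim, us_onset = 0) {
  t_core <- new_trace(sim$time_s, sim$t_core, "degC")
  vo2 <- new_trace(sim$time_s, sim$vo2, "ml_per_min")
  rq <- rq_trace(new_trace(sim$time_s, sim$vco2, "ml_per_min"), vo2)
  onset <- uih_onset(t_core, us_onset)
  end <- if (is.na(onset)) NA_real_ else uih_end(t_core, after = onset)
  tibble::tibble(
    endpoint = c("max_delta_t_core", "max_delta_vo2", "max_delta_rq",
                 "uih_onset_s", "uih_end_s", "uih_duration_min"),
    value = c(max_delta(t_core, endpoint_config("t_core"), us_onset),
              max_delta(vo2, endpoint_config("vo2"), us_onset),
              max_delta_rq(rq, us_onset),
              onset, end, uih_duration(onset, end)),
    unit = c("degC", "ml_per_min", "ratio", "s", "s", "min")
  )
}
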