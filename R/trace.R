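#' Construct a unit-tagged time series
#'
#' The package's common currency for physiological signals (core temperature,
#' BAT surface temperature, VO2, VCO2, RQ, photometry) is a tibble with a
#' `time_s` column, a `value` column and a `unit` attribute. Times must be
#' strictly increasing; sampling may be irregular.
#'
#' @param time_s numeric vector of sample times in seconds, strictly increasing
#' @param value numeric vector, same length as `time_s`
#' @param unit unit tag, one of `"degC"`, `"ml_per_min"`, `"ratio"`, `"au"`,
#'   `"bpm"`, `"z"` (free-form strings are accepted but these are used
#'   throughout)
#' @return a tibble of class `uih_trace` with columns `time_s`, `value`
#' @export
#' @examples
#' tr <- new_trace(0:9, rnorm(10, 37), "degC")
#' trace_unit(tr)
new_trace <- function(time_s, value, unit = "au") {
  time_s <- as.numeric(time_s)
  value <- as.numeric(value)
  if (length(time_s) != length(value)) {
    stop("`time_s` and `value` must have equal length", call. = FALSE)
  }
  if (anyNA(time_s) || any(!is.finite(time_s))) {
    stop("`time_s` must be finite", call. = FALSE)
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_s = time_s, value = value)
  attr(out, "unit") <- as.character(unit)[1]
  class(out) <- c("uih_trace", class(out))
  out
}

#' @rdname new_trace
#' @param x object to test or query
#' @export
is_trace <- function(x) inherits(x, "uih_trace")

#' @rdname new_trace
#' @export
trace_unit <- function(x) attr(x, "unit") %||% "au"

# Coerce a plain data frame with time_s/value columns; used at most entry
# points so piped tibbles work without explicit construction.
as_trace <- function(x, unit = NULL) {
  if (is_trace(x) && is.null(unit)) return(x)
  if (!is.data.frame(x) || !all(c("time_s", "value") %in% names(x))) {
    stop("expected a trace: a data frame with `time_s` and `value` columns",
         call. = FALSE)
  }
  new_trace(x$time_s, x$value, unit %||% attr(x, "unit") %||% "au")
}

# Sampling interval of a uniformly sampled trace; errors otherwise.
trace_dt <- function(trace, tol = 1e-6) {
  d <- diff(trace$time_s)
  if (length(d) == 0) stop("trace has fewer than 2 samples", call. = FALSE)
  if (max(d) - min(d) > tol * stats::median(d)) {
    stop("trace is not uniformly sampled; resample first", call. = FALSE)
  }
  stats::median(d)
}

#' Plot a trace
#'
#' @param object a `uih_trace`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.uih_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = trace_unit(object))
}
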