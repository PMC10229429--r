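#' De-bleach a photometry trace
#'
#' Removes the slow photobleaching decay with a zero-phase Butterworth
#' high-pass filter (2nd order, 0.01 Hz by default). The output is
#' approximately zero-mean.
#'
#' @param trace data frame with `time_s`, `value`, uniformly sampled
#' @param highpass_cutoff_hz cutoff, Hz; must be below Nyquist
#' @param order filter order
#' @return de-bleached trace
#' @export
debleach <- function(trace, highpass_cutoff_hz = 0.01, order = 2) {
  butter_zero_phase(trace, highpass_cutoff_hz, order, "high")
}

#' z-score a trace
#'
#' `(x - mean(x)) / sd(x)` over the whole recording, with the sample
#' (n - 1) standard deviation. A constant trace returns all zeros with a
#' warning.
#'
#' @param trace data frame with `time_s`, `value`
#' @return trace in z units
#' @export
zscore <- function(trace) {
  trace <- as_trace(trace)
  if (nrow(trace) < 2) stop("need >= 2 samples", call. = FALSE)
  s <- sd(trace$value)
  if (s == 0) {
    warning("constant trace; z scores set to 0", call. = FALSE)
    return(new_trace(trace$time_s, rep(0, nrow(trace)), "z"))
  }
  new_trace(trace$time_s, (trace$value - mean(trace$value)) / s, "z")
}

#' Detect peaks by topographic prominence
#'
#' Local maxima whose prominence is at least `min_prominence`. Prominence of
#' a peak is its height minus the higher of the two minima separating it from
#' higher ground on each side (trace edges count as ground level). Plateau
#' maxima are reported once, at the first sample of the plateau.
#'
#' @param trace data frame with `time_s`, `value`
#' @param min_prominence minimum prominence, same unit as the trace
#'   (default 2, intended for z-scored traces)
#' @param min_height optional minimum peak value; `-Inf` disables. On
#'   z-scored traces a height floor suppresses small noise bumps whose
#'   topographic prominence is inflated by the deep valleys between real
#'   transients
#' @return tibble of class `peak_set`: `time_s`, `amplitude`, `prominence`
#' @export
#' @examples
#' tr <- new_trace(1:11, c(0, 0, 1, 3, 1, 0, 0, 2, 0, 0, 0), "z")
#' detect_peaks(tr, min_prominence = 1)
detect_peaks <- function(trace, min_prominence = 2, min_height = -Inf) {
  trace <- as_trace(trace)
  x <- trace$value
  if (any(!is.finite(x))) stop("trace must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3) {
    return(structure(tibble::tibble(time_s = numeric(0),
                                    amplitude = numeric(0),
                                    prominence = numeric(0)),
                     class = c("peak_set", class(tibble::tibble()))))
  }
  # candidate local maxima, plateaus collapsed to their first sample
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prom <- vapply(cand, function(p) {
    h <- x[p]
    # walk left to the first strictly higher sample (or edge)
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- min(left[(if (length(higher_l)) max(higher_l) else 1L):(p - 1L)])
    right <- x[(p + 1L):n]
    higher_r <- which(right > h)
    rmin <- min(right[1L:(if (length(higher_r)) min(higher_r) else
      length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & x[cand] >= min_height
  structure(tibble::tibble(time_s = trace$time_s[cand[keep]],
                           amplitude = x[cand[keep]],
                           prominence = prom[keep]),
            class = c("peak_set", class(tibble::tibble())))
}

#' Refine detected peaks to their rise onsets
#'
#' For each detected peak, walks back from the apex to the last sample whose
#' value lies below `frac` of the peak amplitude; the onset is the following
#' sample (the first on the rise). Calcium transients rise much faster than
#' they decay, so the apex of a noisy (or smoothed) transient is poorly
#' localized while the rise is sharp; comparisons against programmed
#' transient times should use these onsets.
#'
#' @param trace the trace the peaks were detected on (or a sharper version
#'   of it, e.g. before smoothing), same time base
#' @param peaks a [detect_peaks()] result
#' @param frac rise threshold as a fraction of each peak amplitude
#' @return `peaks` with an added `onset_s` column
#' @export
peak_onsets <- function(trace, peaks, frac = 0.5) {
  trace <- as_trace(trace)
  onset <- vapply(seq_len(nrow(peaks)), function(k) {
    apex <- which.min(abs(trace$time_s - peaks$time_s[k]))
    thr <- frac * peaks$amplitude[k]
    i <- apex
    while (i > 1 && trace$value[i - 1] >= thr) i <- i - 1
    trace$time_s[i]
  }, numeric(1))
  peaks$onset_s <- onset
  peaks
}

#' Per-window window specification for stimulus-locked statistics
#'
#' The before/during/after analysis windows around one stimulus: 5 s
#' immediately before onset, 10 s from onset (the stimulus duration), and
#' 15 s immediately after offset.
#'
#' @param before_s,during_s,after_s window durations, s (> 0)
#' @return list of class `window_spec`
#' @export
window_spec <- function(before_s = 5, during_s = 10, after_s = 15) {
  assert_number(before_s, "before_s", 0, strict_lower = TRUE)
  assert_number(during_s, "during_s", 0, strict_lower = TRUE)
  assert_number(after_s, "after_s", 0, strict_lower = TRUE)
  structure(list(before_s = before_s, during_s = during_s, after_s = after_s),
            class = "window_spec")
}

window_bounds <- function(spec, us_onset, us_offset) {
  list(before = c(us_onset - spec$before_s, us_onset),
       during = c(us_onset, us_onset + spec$during_s),
       after = c(us_offset, us_offset + spec$after_s))
}

#' Stimulus-locked window statistics
#'
#' For each of the before/during/after windows: the largest detected-peak
#' amplitude in the window (0 when the window holds no peak), the mean of the
#' z-scored trace, and the peak rate in peaks per minute.
#'
#' @param ztrace z-scored trace
#' @param peaks a [detect_peaks()] result
#' @param us_onset,us_offset stimulus on/off times, absolute s
#' @param spec a [window_spec()]
#' @return tibble: `window`, `peak_amplitude`, `mean_z`, `peak_freq_per_min`,
#'   `n_peaks`
#' @export
window_stats <- function(ztrace, peaks, us_onset, us_offset,
                         spec = window_spec()) {
  ztrace <- as_trace(ztrace)
  bounds <- window_bounds(spec, us_onset, us_offset)
  span <- range(ztrace$time_s)
  purrr::imap_dfr(bounds, function(w, name) {
    if (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9) {
      stop(sprintf("'%s' window [%g, %g) lies outside the trace", name,
                   w[1], w[2]), call. = FALSE)
    }
    sel_z <- in_window(ztrace$time_s, w)
    sel_p <- in_window(peaks$time_s, w)
    np <- sum(sel_p)
    tibble::tibble(
      window = name,
      peak_amplitude = if (np) max(peaks$amplitude[sel_p]) else 0,
      mean_z = mean(ztrace$value[sel_z]),
      peak_freq_per_min = np / ((w[2] - w[1]) / 60),
      n_peaks = np
    )
  })
}

#' Average window statistics across the stimuli of a train
#'
#' Computes [window_stats()] per stimulus of a schedule and averages each
#' statistic across stimuli, the per-pulse aggregation used for multi-pulse
#' trains.
#'
#' @param ztrace z-scored trace
#' @param peaks a [detect_peaks()] result
#' @param schedule stimulus schedule tibble (`onset_s`, `offset_s`)
#' @param spec a [window_spec()]
#' @return tibble as [window_stats()], averaged across stimuli
#' @export
train_window_stats <- function(ztrace, peaks, schedule,
                               spec = window_spec()) {
  stats_all <- purrr::map2_dfr(schedule$onset_s, schedule$offset_s,
                               function(on, off) {
    window_stats(ztrace, peaks, on, off, spec)
  })
  stats_all |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$window, c("before", "during", "after")))
}

#' Onset time of evoked activity
#'
#' Time from the stimulus onset to the first sample whose z score strictly
#' exceeds mean + 3 SD of the pre-stimulus window (the `pre_window_s` seconds
#' right before onset). `NA` when never exceeded.
#'
#' @param ztrace z-scored trace
#' @param us_onset stimulus onset, absolute s
#' @param pre_window_s pre-stimulus baseline length, s
#' @return onset latency in seconds (relative to `us_onset`), or `NA`
#' @export
onset_time <- function(ztrace, us_onset, pre_window_s = 5) {
  ztrace <- as_trace(ztrace)
  sel <- in_window(ztrace$time_s, c(us_onset - pre_window_s, us_onset))
  if (sum(sel) < 2) stop("need >= 2 pre-stimulus samples", call. = FALSE)
  thr <- mean(ztrace$value[sel]) + 3 * sd(ztrace$value[sel])
  post <- ztrace$time_s >= us_onset & ztrace$value > thr
  if (!any(post)) return(NA_real_)
  ztrace$time_s[which(post)[1]] - us_onset
}

#' Baseline-normalized fluorescence change
#'
#' `(F - F0) / F0` with `F0` the mean over `f0_window` (absolute seconds,
#' half-open). Errors if `F0 <= 0`.
#'
#' @param trace raw fluorescence trace
#' @param f0_window c(start, end), absolute s
#' @return dF/F trace (unit `"ratio"`)
#' @export
dff <- function(trace, f0_window) {
  trace <- as_trace(trace)
  f0 <- baseline_mean(trace, f0_window)
  if (f0 <= 0) stop("F0 <= 0; cannot normalize", call. = FALSE)
  new_trace(trace$time_s, (trace$value - f0) / f0, "ratio")
}

#' Onset of evoked calcium activity on a dF/F trace
#'
#' Same rule as [onset_time()] applied to dF/F: first sample with
#' dF/F > mean + 3 SD of the pre-stimulus window.
#'
#' @param dff_trace a [dff()] trace
#' @param us_onset stimulus onset, absolute s
#' @param pre_window_s pre-stimulus baseline length, s
#' @return onset latency in seconds, or `NA`
#' @export
cell_onset_time <- function(dff_trace, us_onset, pre_window_s = 5) {
  onset_time(dff_trace, us_onset, pre_window_s)
}
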