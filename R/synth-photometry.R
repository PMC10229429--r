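#' Simulate a bleaching photometry trace with stimulus-locked transients
#'
#' Signal model: `A * exp(-t / bleach_tau)` photobleaching baseline, plus one
#' exponentially decaying transient kernel
#' `amp * exp(-(t - t0) / transient_tau)` per entry of `transient_times`
#' (instantaneous rise, so the detrended maximum of an isolated transient sits
#' exactly at its programmed onset), plus white Gaussian noise.
#'
#' @param bleach_tau photobleaching time constant, s
#' @param bleach_amp bleaching baseline amplitude, a.u.
#' @param transient_times transient onset times, s, within [0, duration_s]
#' @param transient_amp transient amplitude(s), a.u. (recycled)
#' @param transient_tau transient decay constant, s
#' @param noise_sd noise SD, a.u.
#' @param fs sampling rate, Hz
#' @param duration_s recording length, s
#' @param seed integer seed
#' @return list with `trace` (a [new_trace()] in a.u.) and `truth`
#'   (`transient_times`, `transient_amp`, `seed`)
#' @export
#' @examples
#' sim <- simulate_photometry(transient_times = c(10, 20), seed = 3)
#' nrow(sim$trace)
simulate_photometry <- function(bleach_tau = 120,
                                bleach_amp = 2,
                                transient_times = numeric(0),
                                transient_amp = 1,
                                transient_tau = 1.5,
                                noise_sd = 0.02,
                                fs = 20,
                                duration_s = 60,
                                seed = 1L) {
  assert_number(fs, "fs", 0, strict_lower = TRUE)
  assert_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", 0)
  if (length(transient_times) &&
      (min(transient_times) < 0 || max(transient_times) > duration_s)) {
    stop("`transient_times` must lie within [0, duration_s]", call. = FALSE)
  }
  t <- seq(0, duration_s, by = 1 / fs)
  y <- bleach_amp * exp(-t / bleach_tau)
  amp <- rep_len(transient_amp, length(transient_times))
  for (k in seq_along(transient_times)) {
    on <- t >= transient_times[k]
    y[on] <- y[on] + amp[k] * exp(-(t[on] - transient_times[k]) / transient_tau)
  }
  set.seed(derive_seed(seed))
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  list(
    trace = new_trace(t, y, "au"),
    truth = list(transient_times = transient_times, transient_amp = amp,
                 seed = seed)
  )
}
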