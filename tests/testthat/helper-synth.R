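# Shared test helpers: small constructors used across files.

uniform_trace <- function(values, dt = 1, t0 = 0, unit = "au") {
  new_trace(t0 + (seq_along(values) - 1) * dt, values, unit)
}

# Brute-force disk mean: the independent oracle for roi_mean/tail_roi_mean.
brute_disk_mean <- function(frame, center, radius_mm, pixel_size_mm) {
  acc <- c(); r_px <- radius_mm / pixel_size_mm
  for (r in seq_len(nrow(frame))) {
    for (cc in seq_len(ncol(frame))) {
      if ((r - center[1])^2 + (cc - center[2])^2 <= r_px^2) {
        acc <- c(acc, frame[r, cc])
      }
    }
  }
  if (length(acc) == 0) return(NA_real_)
  mean(acc)
}

# Brute-force prominence peak finder: exhaustive scan, the oracle for
# detect_peaks.
brute_peaks <- function(x, min_prominence) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        h <- x[i]
        lh <- which(x[seq_len(i - 1L)] > h)
        lstart <- if (length(lh)) max(lh) else 1L
        lmin <- min(x[lstart:(i - 1L)])
        rh <- which(x[(j + 1L):n] > h)
        rend <- if (length(rh)) j + min(rh) else n
        rmin <- min(x[(j + 1L):rend])
        if (h - max(lmin, rmin) >= min_prominence) out <- c(out, i)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# One standard small rendered video for pipeline tests.
small_video <- function(dip = 2, noise_sd = 0.1, seed = 1, dt = 5) {
  t <- seq(-900, 780, by = dt)
  tb <- new_trace(t, 35 - dip * exp(-((t - 570)^2) / (2 * 120^2)), "degC")
  render_thermal_video(tb, t_body = 34, noise_sd = noise_sd, seed = seed)
}
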