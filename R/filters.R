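# Zero-phase IIR filtering.
#
# Coefficients come from signal::butter; the application is done here with
# steady-state initial conditions (so a constant trace passes through
# unchanged) and odd reflection padding, which signal::filtfilt does not do
# and which otherwise leaves large edge transients.

# Steady-state filter delays for unit step input (direct form II transposed).
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[2:n] - a[2:n] * b[1]
  solve(IminusA, B)
}

# Direct-form-II-transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  if (n == 1) return(b[1] * x)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      z[1:(n - 2)] <- b[2:(n - 1)] * xi + z[2:(n - 1)] - a[2:(n - 1)] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Zero-phase filtering: forward-backward pass over an odd-reflection-padded
# signal, each pass started from scaled steady-state conditions.
zero_phase_filter <- function(b, a, x) {
  n <- max(length(b), length(a))
  pad <- 3 * (n - 1)
  nx <- length(x)
  if (nx <= pad) {
    stop(sprintf("trace too short for the filter (need > %d samples)", pad),
         call. = FALSE)
  }
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[nx] - x[(nx - 1):(nx - pad)])
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + nx)]
}

# Shared Butterworth front end for lowpass()/debleach().
butter_zero_phase <- function(trace, cutoff_hz, order, type) {
  trace <- as_trace(trace)
  dt <- trace_dt(trace)
  nyq <- 1 / (2 * dt)
  assert_number(cutoff_hz, "cutoff_hz", 0, strict_lower = TRUE)
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff %.4g Hz is at or above the Nyquist frequency %.4g Hz",
                 cutoff_hz, nyq), call. = FALSE)
  }
  flt <- signal::butter(order, cutoff_hz / nyq, type)
  y <- zero_phase_filter(flt$b, flt$a, trace$value)
  new_trace(trace$time_s, y, trace_unit(trace))
}
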