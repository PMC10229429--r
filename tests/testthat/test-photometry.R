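test_that("debleach removes DC and slow decay but keeps fast transients", {
  const <- uniform_trace(rep(3, 400), dt = 0.05)
  out <- debleach(const, 0.5)
  expect_lt(max(abs(out$value)), 1e-9)

  t <- seq(0, 600, by = 0.5)
  slow <- new_trace(t, 2 * exp(-t / 300), "au")    # tau 300 s vs 0.05 Hz
  hp <- debleach(slow, 0.05)
  expect_lt(max(abs(hp$value[100:1000])), 0.1 * diff(range(slow$value)))

  t2 <- seq(0, 600, by = 0.25)
  fast <- new_trace(t2, exp(-(t2 - 300)^2 / (2 * 0.3^2)), "au")  # ~0.3 s
  hp2 <- debleach(fast, 0.05)
  expect_gt(max(hp2$value), 0.9)
})

test_that("zscore matches hand arithmetic and is idempotent", {
  tr <- uniform_trace(c(1, 2, 3))
  expect_equal(zscore(tr)$value, c(-1, 0, 1))   # sample SD convention
  expect_warning(z0 <- zscore(uniform_trace(rep(5, 10))), "constant")
  expect_equal(z0$value, rep(0, 10))
  set.seed(6)
  z1 <- zscore(uniform_trace(rnorm(100)))
  expect_equal(mean(z1$value), 0, tolerance = 1e-12)
  expect_equal(sd(z1$value), 1, tolerance = 1e-12)
  z2 <- zscore(z1)
  expect_lt(max(abs(z2$value - z1$value)), 1e-12)
})

test_that("detect_peaks: monotone empty, triangle apex, oracle equality", {
  mono <- uniform_trace(1:50)
  expect_equal(nrow(detect_peaks(mono, 0.1)), 0)

  tri <- uniform_trace(c(rep(0, 5), 1, 2, 3, 2, 1, rep(0, 5)))
  pk <- detect_peaks(tri, min_prominence = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$time_s, 7)           # apex sample (0-based times, dt 1)
  expect_equal(pk$amplitude, 3)
  expect_equal(pk$prominence, 3)

  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(120)
    prom <- runif(1, 0.2, 2.5)
    got <- detect_peaks(uniform_trace(x), prom)
    want_idx <- brute_peaks(x, prom)
    expect_equal(nrow(got), length(want_idx))
    expect_equal(got$time_s, want_idx - 1)
  }
})

test_that("window_stats computes per-window amplitude, mean and rate", {
  t <- seq(-10, 40, by = 0.1)
  z <- new_trace(t, rep(0, length(t)), "z")
  peaks <- tibble::tibble(time_s = c(2, 20), amplitude = c(4, 3),
                          prominence = c(4, 3))
  ws <- window_stats(z, peaks, us_onset = 0, us_offset = 10)
  before <- ws[ws$window == "before", ]
  during <- ws[ws$window == "during", ]
  after <- ws[ws$window == "after", ]
  expect_equal(before$peak_freq_per_min, 0)      # no peaks before
  expect_equal(before$peak_amplitude, 0)
  expect_equal(during$n_peaks, 1)
  expect_equal(during$peak_freq_per_min, 6)      # 1 peak / (10/60) min
  expect_equal(during$peak_amplitude, 4)
  expect_equal(after$peak_freq_per_min, 4)       # 1 peak / (15/60) min
  expect_error(window_stats(z, peaks, -100, 10), "outside")

  # brute-force recount on random peak sets
  set.seed(19)
  for (i in 1:30) {
    pk <- tibble::tibble(time_s = sort(runif(10, -10, 40)),
                         amplitude = rnorm(10, 3), prominence = rep(1, 10))
    ws <- window_stats(z, pk, 0, 10)
    for (w in list(c(-5, 0, "before"), c(0, 10, "during"),
                   c(10, 25, "after"))) {
      sel <- pk$time_s >= as.numeric(w[1]) & pk$time_s < as.numeric(w[2])
      row <- ws[ws$window == w[3], ]
      expect_equal(row$n_peaks, sum(sel))
      expect_equal(row$peak_freq_per_min,
                   sum(sel) / ((as.numeric(w[2]) - as.numeric(w[1])) / 60))
      if (any(sel)) expect_equal(row$peak_amplitude, max(pk$amplitude[sel]))
    }
    expect_true(all(ws$peak_freq_per_min >= 0))
    mins <- c(5, 10, 15) / 60
    expect_equal(ws$peak_freq_per_min * mins, round(ws$peak_freq_per_min * mins),
                 tolerance = 1e-9)
  }
})

test_that("onset_time applies the mean + 3 SD rule against the pre-window", {
  # constructed pre-window with mean 0, SD 1; first crossing 1.17 s after onset
  pre_t <- seq(-5, -0.01, by = 0.01)
  pre_v <- rep(c(-1, 1), length.out = length(pre_t))  # mean 0, SD ~1
  post_t <- seq(0, 5, by = 0.01)
  post_v <- ifelse(post_t >= 1.17, 5, 0)
  z <- new_trace(c(pre_t, post_t), c(pre_v, post_v), "z")
  got <- onset_time(z, us_onset = 0)
  expect_equal(got, 1.17, tolerance = 1e-9)

  never <- new_trace(c(pre_t, post_t), c(pre_v, rep(0, length(post_t))), "z")
  expect_true(is.na(onset_time(never, 0)))

  set.seed(29)
  for (i in 1:30) {
    t <- seq(-5, 10, by = 0.05)
    v <- rnorm(length(t))
    z <- new_trace(t, v, "z")
    pre <- v[t >= -5 & t < 0]
    thr <- mean(pre) + 3 * sd(pre)
    hit <- which(t >= 0 & v > thr)
    want <- if (length(hit)) t[hit[1]] else NA_real_
    expect_equal(onset_time(z, 0), want)
  }
})

test_that("dff normalizes to the F0 window and is scale invariant", {
  tr <- uniform_trace(rep(2, 100), dt = 0.1)
  expect_equal(dff(tr, c(0, 5))$value, rep(0, 100))
  tr2 <- uniform_trace(c(rep(2, 50), rep(4, 50)), dt = 0.1)
  expect_equal(dff(tr2, c(0, 5))$value[51:100], rep(1, 50))
  scaled <- uniform_trace(5 * tr2$value, dt = 0.1)
  expect_equal(dff(scaled, c(0, 5))$value, dff(tr2, c(0, 5))$value)
  neg <- uniform_trace(rep(-1, 100), dt = 0.1)
  expect_error(dff(neg, c(0, 5)), "F0")
})

test_that("cell_onset_time mirrors onset_time on dF/F traces", {
  t <- seq(-5, 10, by = 0.1)
  f <- ifelse(t >= 2, 30, 10) + rep(c(-0.1, 0.1), length.out = length(t))
  d <- dff(new_trace(t, f, "au"), c(-5, 0))
  got <- cell_onset_time(d, 0)
  expect_equal(got, 2, tolerance = 0.0501)
})

test_that("pipeline recovers programmed transients after debleach + zscore", {
  hits <- 0
  for (seed in 1:25) {
    truth_times <- c(5, 12, 19, 26)
    sim <- simulate_photometry(bleach_tau = 60, transient_times = truth_times,
                               transient_amp = 0.5, noise_sd = 0.05,
                               fs = 20, duration_s = 40, seed = seed)
    z <- zscore(lowpass(debleach(sim$trace, 0.05), 4))
    pk <- peak_onsets(z, detect_peaks(z, min_prominence = 2, min_height = 2))
    ok <- nrow(pk) == length(truth_times) &&
      all(abs(pk$onset_s - truth_times) <= 2 / 20 + 1e-9)
    hits <- hits + ok
  }
  expect_gte(hits, 24)
})

test_that("peak_onsets walks back to the rise of each transient", {
  x <- c(rep(0, 10), 0.2, 4, 3.5, 3, 2, 1, rep(0, 10))
  tr <- uniform_trace(x)
  pk <- detect_peaks(tr, min_prominence = 2)
  expect_equal(nrow(pk), 1)
  ons <- peak_onsets(tr, pk)
  expect_equal(ons$onset_s, 11)   # first sample at/above half height
})
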