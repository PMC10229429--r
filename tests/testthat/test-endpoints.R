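test_that("baseline_mean averages exactly the half-open window", {
  tr <- uniform_trace(rep(37, 50), dt = 10, t0 = -250)
  expect_equal(baseline_mean(tr, c(-250, 0)), 37)
  two <- new_trace(c(-100, -50), c(36, 38), "degC")
  expect_equal(baseline_mean(two, c(-100, 0)), 37)
  # half-open: a sample exactly at the window end is excluded
  three <- new_trace(c(-100, -50, 0), c(36, 38, 100), "degC")
  expect_equal(baseline_mean(three, c(-100, 0)), 37)
  expect_error(baseline_mean(two, c(-500, -400)), "no baseline")
  # brute-force equality on random irregular traces
  set.seed(31)
  for (i in 1:50) {
    t <- sort(runif(40, -300, 300)); t <- t[!duplicated(t)]
    v <- rnorm(length(t))
    tr <- new_trace(t, v, "au")
    w <- sort(runif(2, -300, 300))
    sel <- t >= w[1] & t < w[2]
    if (!any(sel)) {
      expect_error(baseline_mean(tr, w), "no baseline")
    } else {
      expect_identical(baseline_mean(tr, w), mean(v[sel]))
    }
  }
})

test_that("max_delta reproduces forced arithmetic and the zero case", {
  flat <- uniform_trace(rep(36, 300), dt = 10, t0 = -600)
  expect_equal(max_delta(flat, endpoint_config("t_core"), 0), 0)

  # baseline pinned at 37.0, window minimum 33.74 -> -3.26
  t <- seq(-360, 1790, by = 10)
  v <- rep(37, length(t))
  v[t >= 0] <- 35
  v[t == 900] <- 33.74
  tr <- new_trace(t, v, "degC")
  expect_equal(max_delta(tr, endpoint_config("t_core"), 0), -3.26)
})

test_that("max_delta equals a brute-force scan on random traces", {
  set.seed(17)
  cfg <- endpoint_config("t_bat")
  for (i in 1:200) {
    t <- sort(runif(60, -1000, 1000)); t <- t[!duplicated(t)]
    v <- rnorm(length(t), 34, 2)
    tr <- new_trace(t, v, "degC")
    base_sel <- t >= -900 & t < 0
    win_sel <- t >= 420 & t < 720
    if (!any(base_sel) || !any(win_sel)) next
    want <- min(v[win_sel]) - mean(v[base_sel])
    expect_equal(max_delta(tr, cfg, 0), want, tolerance = 1e-12)
    # bound: never below global min - global max
    expect_gte(max_delta(tr, cfg, 0), min(v) - max(v))
  }
})

test_that("endpoints are invariant to a constant time shift", {
  set.seed(23)
  t <- seq(-900, 1800, by = 15)
  v <- 37 - 3 * exp(-(t - 600)^2 / 1e5) + rnorm(length(t), 0, 0.05)
  tr <- new_trace(t, v, "degC")
  for (shift in c(-1234.5, 0, 987)) {
    tr2 <- new_trace(t + shift, v, "degC")
    expect_equal(max_delta(tr2, endpoint_config("t_core"), shift),
                 max_delta(tr, endpoint_config("t_core"), 0))
    expect_equal(uih_onset(tr2, shift) - shift, uih_onset(tr, 0))
  }
})

test_that("rq_trace divides aligned samples and NaNs non-positive VO2", {
  t <- 0:9
  vo2 <- new_trace(t, rep(1, 10), "ml_per_min")
  vco2 <- new_trace(t, rep(0.72, 10), "ml_per_min")
  rq <- rq_trace(vco2, vo2)
  expect_equal(rq$value, rep(0.72, 10))
  expect_equal(rq_trace(vo2, vo2)$value, rep(1, 10))
  vo2z <- new_trace(t, c(rep(1, 5), 0, rep(1, 4)), "ml_per_min")
  rqz <- rq_trace(vco2, vo2z)
  expect_true(is.nan(rqz$value[6]))
  far <- new_trace(t + 1e6, rep(1, 10), "ml_per_min")
  expect_error(rq_trace(vco2, far), "overlap")
})

test_that("max_delta_rq uses the 45-55 min window against its 28-min baseline", {
  t <- seq(-1800, 3600, by = 60)
  v <- rep(0.85, length(t))
  v[t >= 2700 & t < 3300] <- 0.72
  rq <- new_trace(t, v, "ratio")
  expect_equal(max_delta_rq(rq, 0), -0.13)
  expect_equal(max_delta_rq(new_trace(t, rep(0.8, length(t)), "ratio"), 0), 0)
})

test_that("uih_onset crosses at baseline mean - 2 SD and scans like brute force", {
  # constant baseline (SD 0): the first lower sample is the onset
  t <- seq(-360, 600, by = 60)
  v <- rep(37, length(t)); v[t == 300] <- 36.9
  expect_equal(uih_onset(new_trace(t, v, "degC"), 0), 300)
  expect_true(is.na(uih_onset(new_trace(t, rep(37, length(t)), "degC"), 0)))
  expect_error(uih_onset(new_trace(c(-100, 10), c(37, 36), "degC"), 0),
               "baseline")
  set.seed(41)
  for (i in 1:50) {
    t <- seq(-360, 1800, by = 30)
    v <- rnorm(length(t), 37, 0.2) - 3 * (t > 400) * runif(1)
    tr <- new_trace(t, v, "degC")
    base <- v[t >= -360 & t < -60]
    thr <- mean(base) - 2 * sd(base)
    hit <- which(t >= 0 & v < thr)
    want <- if (length(hit)) t[hit[1]] else NA_real_
    expect_identical(uih_onset(tr, 0), want)
  }
})

test_that("uih_end finds the return to 34 degC and duration converts to min", {
  t <- seq(0, 200, by = 10)
  always_warm <- new_trace(t, rep(36, length(t)), "degC")
  expect_true(is.na(uih_end(always_warm, 0)))
  step <- new_trace(t, ifelse(t < 100, 33, 35), "degC")
  expect_equal(uih_end(step, 0), 100)
  expect_equal(uih_duration(0, 3120), 52)
  expect_true(is.na(uih_duration(NA_real_, 3120)))
  expect_error(uih_end(step, after = 1e6), "extend")
})

test_that("bout endpoints recover programmed kinetics from the plant", {
  sch <- build_train(controller_config()$train, 600)
  # dip depth is window-based and robust to telemetry noise
  noisy <- simulate_plant(plant_params(noise_sd = 0.05), sch,
                          duration_min = 200, seed = 12)
  rep <- endpoint_report(noisy, us_onset = 600)
  val <- function(k) rep$value[rep$endpoint == k]
  expect_lt(abs(val("max_delta_t_core") - (-3.24)), 0.25)
  # bout duration is a threshold-crossing time; assess it on the
  # deterministic trajectory
  clean <- simulate_plant(plant_params(noise_sd = 0, vo2_noise_sd = 0), sch,
                          duration_min = 200, seed = 12)
  repc <- endpoint_report(clean, us_onset = 600)
  dur <- repc$value[repc$endpoint == "uih_duration_min"]
  expect_gt(dur, 35)
  expect_lt(dur, 70)
})
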