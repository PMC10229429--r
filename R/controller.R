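#' Closed-loop controller configuration
#'
#' Bang-bang body-temperature control: the controller samples T_core every
#' `sample_interval_min` minutes and fires one ultrasound train whenever the
#' sample exceeds `T_set` (strictly) and no train is already in progress.
#' Default train parameters follow the long-duration feedback protocol
#' (1.6 MPa, 50% duty, 10 Hz PRF, 10 s stimuli, 20 s inter-stimulus gap, 6
#' stimuli); after `escalation$after_h` hours the pressure is multiplied by
#' `escalation$pressure_multiplier` and the stimulus count becomes
#' `escalation$n_stimuli_new` (compensating for acoustic coupling loss over
#' long sessions).
#'
#' @param t_set target core temperature, degC
#' @param sample_interval_min telemetry sampling interval, min
#' @param train list: `pressure_mpa`, `duty`, `prf_hz`, `stimulus_duration_s`,
#'   `isi_s` (off-gap between consecutive stimuli), `n_stimuli`
#' @param escalation list: `after_h`, `pressure_multiplier`, `n_stimuli_new`;
#'   `NULL` disables escalation
#' @return list of class `controller_config`
#' @export
controller_config <- function(t_set = 34,
                              sample_interval_min = 1,
                              train = list(pressure_mpa = 1.6, duty = 0.5,
                                           prf_hz = 10,
                                           stimulus_duration_s = 10,
                                           isi_s = 20, n_stimuli = 6),
                              escalation = list(after_h = 12,
                                                pressure_multiplier = 1.1,
                                                n_stimuli_new = 8)) {
  assert_number(t_set, "t_set", 20, 40)
  assert_number(sample_interval_min, "sample_interval_min", 0,
                strict_lower = TRUE)
  assert_number(train$pressure_mpa, "train$pressure_mpa", 0)
  assert_number(train$duty, "train$duty", 0, 1, strict_lower = TRUE)
  assert_number(train$stimulus_duration_s, "train$stimulus_duration_s", 0,
                strict_lower = TRUE)
  assert_number(train$isi_s, "train$isi_s", 0)
  assert_number(train$n_stimuli, "train$n_stimuli", 1)
  if (!is.null(escalation)) {
    assert_number(escalation$after_h, "escalation$after_h", 0)
    assert_number(escalation$pressure_multiplier,
                  "escalation$pressure_multiplier", 0, strict_lower = TRUE)
    assert_number(escalation$n_stimuli_new, "escalation$n_stimuli_new", 1)
  }
  structure(list(t_set = t_set, sample_interval_min = sample_interval_min,
                 train = train, escalation = escalation),
            class = "controller_config")
}

#' One bang-bang control decision
#'
#' Fire if and only if the sampled core temperature strictly exceeds the
#' setpoint; at or below the setpoint the ultrasound stays off. A
#' non-finite sample holds (fail-safe) with a warning.
#'
#' @param t_core_sample sampled core temperature, degC
#' @param t_set setpoint, degC
#' @return `"fire"` or `"hold"`
#' @export
#' @examples
#' control_step(36.2, 34)
#' control_step(34.0, 34)
control_step <- function(t_core_sample, t_set = 34) {
  if (!is.finite(t_core_sample)) {
    warning("non-finite T_core sample; holding", call. = FALSE)
    return("hold")
  }
  if (t_core_sample > t_set) "fire" else "hold"
}

#' Build the stimulus schedule of one ultrasound train
#'
#' `n_stimuli` on-intervals of `stimulus_duration_s` separated by `isi_s`
#' off-gaps, starting at `t0_s`; onset-to-onset period is therefore
#' `stimulus_duration_s + isi_s` (30 s with the defaults).
#'
#' @param train the `train` element of a [controller_config()]
#' @param t0_s train start, absolute s
#' @param train_id identifier attached to every event of the train
#' @return tibble: `onset_s`, `offset_s`, `pressure_mpa`, `train_id`
#' @export
#' @examples
#' build_train(controller_config()$train, 0)
build_train <- function(train, t0_s, train_id = 1L) {
  stopifnot(is.finite(t0_s))
  period <- train$stimulus_duration_s + train$isi_s
  onsets <- t0_s + period * (seq_len(train$n_stimuli) - 1)
  tibble::tibble(onset_s = onsets,
                 offset_s = onsets + train$stimulus_duration_s,
                 pressure_mpa = train$pressure_mpa,
                 train_id = train_id)
}

train_span_s <- function(train) {
  train$n_stimuli * train$stimulus_duration_s +
    (train$n_stimuli - 1) * train$isi_s
}

#' Run a closed-loop feedback session against the simulated plant
#'
#' Integrates the thermoregulatory plant at `dt_min`, samples the (noisy)
#' core temperature every `cfg$sample_interval_min`, and fires one train per
#' [control_step()] `"fire"` decision; re-triggering is suppressed while a
#' train is in progress. After the escalation time the configured pressure
#' multiplier and new stimulus count apply to subsequent trains. Acoustic
#' pressure feeds back on the plant only through the dose-scaled drive
#' suppression (see [plant_params()]).
#'
#' @param plant a [plant_params()]
#' @param cfg a [controller_config()]
#' @param duration_h session length, hours
#' @param dt_min plant integration step, min
#' @param seed integer seed
#' @return object of class `uih_session`: list with `samples` (tibble:
#'   `time_s`, `t_core`, `decision`, `fired`), `trains` (stimulus schedule
#'   tibble), `plant_traces` (noise-free state tibble: `time_s`, `t_core_true`,
#'   `drive`), `config`, `plant`, `seed`
#' @export
#' @examples
#' log <- run_closed_loop(plant_params(), controller_config(),
#'                        duration_h = 2, seed = 1)
#' summarize_session(log)
run_closed_loop <- function(plant, cfg = controller_config(), duration_h = 24,
                            dt_min = 0.1, seed = 1L) {
  stopifnot(inherits(plant, "plant_params"),
            inherits(cfg, "controller_config"))
  assert_number(duration_h, "duration_h", 0, strict_lower = TRUE)
  assert_number(dt_min, "dt_min", 0, strict_lower = TRUE)

  n_steps <- ceiling(duration_h * 60 / dt_min) + 1L
  sample_every <- max(1L, round(cfg$sample_interval_min / dt_min))
  set.seed(derive_seed(seed))
  meas_noise <- rnorm(n_steps, 0, plant$noise_sd)

  state <- list(T = plant_equilibrium(plant), H = plant$h0)
  times_min <- (seq_len(n_steps) - 1L) * dt_min
  Tv <- numeric(n_steps); Hv <- numeric(n_steps)

  sample_idx <- integer(0); sample_t <- numeric(0)
  sample_val <- numeric(0); sample_dec <- character(0)
  sample_fired <- logical(0)
  trains <- vector("list", 0)
  train_end_s <- -Inf
  n_trains <- 0L

  for (i in seq_len(n_steps)) {
    t_min <- times_min[i]
    Tv[i] <- state$T; Hv[i] <- state$H
    if (abs(state$T) > 60) {
      stop(sprintf("plant divergence: |T| = %.1f degC at t = %.1f min",
                   state$T, t_min), call. = FALSE)
    }
    if ((i - 1L) %% sample_every == 0L) {
      t_s <- t_min * 60
      meas <- state$T + meas_noise[i]
      dec <- control_step(meas, cfg$t_set)
      fired <- FALSE
      if (dec == "fire" && t_s >= train_end_s) {
        tr <- cfg$train
        if (!is.null(cfg$escalation) &&
            t_min >= cfg$escalation$after_h * 60) {
          tr$pressure_mpa <- tr$pressure_mpa * cfg$escalation$pressure_multiplier
          tr$n_stimuli <- cfg$escalation$n_stimuli_new
        }
        n_trains <- n_trains + 1L
        trains[[n_trains]] <- build_train(tr, t_s, n_trains)
        train_end_s <- t_s + train_span_s(tr)
        state <- plant_apply_train(state, plant, tr$pressure_mpa)
        fired <- TRUE
      }
      sample_idx <- c(sample_idx, i)
      sample_t <- c(sample_t, t_s)
      sample_val <- c(sample_val, meas)
      sample_dec <- c(sample_dec, dec)
      sample_fired <- c(sample_fired, fired)
    }
    state <- plant_step(state, plant, dt_min)
  }

  samples <- tibble::tibble(
    time_s = sample_t, t_core = sample_val,
    decision = sample_dec, fired = sample_fired
  )
  structure(list(
    samples = samples,
    trains = if (n_trains) dplyr::bind_rows(trains) else
      tibble::tibble(onset_s = numeric(0), offset_s = numeric(0),
                     pressure_mpa = numeric(0), train_id = integer(0)),
    plant_traces = tibble::tibble(time_s = times_min * 60, t_core_true = Tv,
                                  drive = Hv),
    config = cfg, plant = plant, seed = seed
  ), class = "uih_session")
}

#' Summarize a closed-loop session
#'
#' Mean T_core over all samples after the first crossing below `threshold`,
#' total time spent below `threshold` (sample intervals summed), and the
#' number of trains fired.
#'
#' @param log a `uih_session` from [run_closed_loop()]
#' @param threshold torpor criterion temperature, degC (default 34)
#' @return tibble: `mean_t_core`, `hours_below_threshold`, `n_trains`
#' @export
summarize_session <- function(log, threshold = 34) {
  stopifnot(inherits(log, "uih_session"))
  s <- log$samples
  below <- s$t_core < threshold
  first <- if (any(below)) which(below)[1] else NA_integer_
  mean_t <- if (is.na(first)) NA_real_ else mean(s$t_core[first:nrow(s)])
  dt_h <- log$config$sample_interval_min / 60
  tibble::tibble(
    mean_t_core = mean_t,
    hours_below_threshold = sum(below) * dt_h,
    n_trains = length(unique(log$trains$train_id))
  )
}

#' @export
#' @method print uih_session
print.uih_session <- function(x, ...) {
  cat(sprintf("<uih_session> %.1f h, %d samples, %d trains, T_set = %.1f degC\n",
              max(x$samples$time_s) / 3600, nrow(x$samples),
              length(unique(x$trains$train_id)), x$config$t_set))
  invisible(x)
}

#' @rdname summarize_session
#' @param x a `uih_session`
#' @param ... unused
#' @export
tidy.uih_session <- function(x, ...) x$samples

#' @rdname summarize_session
#' @export
glance.uih_session <- function(x, ...) summarize_session(x)

#' Plot a closed-loop session
#'
#' Sampled core temperature with the setpoint and each fired train marked.
#'
#' @param object a `uih_session`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.uih_session <- function(object, ...) {
  s <- object$samples
  onsets <- object$trains |>
    dplyr::distinct(.data$train_id, .keep_all = TRUE)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_s / 3600,
                                  y = .data$t_core)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$config$t_set,
                        linetype = "dashed") +
    ggplot2::geom_point(data = dplyr::semi_join(
      s, tibble::tibble(time_s = onsets$onset_s), by = "time_s"),
      color = "hotpink", size = 0.8) +
    ggplot2::labs(x = "time (h)", y = "T_core (degC)")
}
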