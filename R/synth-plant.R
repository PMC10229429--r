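#' Thermoregulatory plant parameters
#'
#' Parameterizes the simulated mouse used as the closed-loop plant and as the
#' source of synthetic physiology traces. The model is first-order Newtonian
#' cooling with a suppressible thermogenic drive H in [0, 1]:
#'
#'   dT/dt = -k_loss (T - T_amb) + k_therm H(t)
#'   dH/dt = (H0 - H) / tau_recovery
#'
#' with H decremented by `suppression_per_train` (scaled by acoustic pressure,
#' see Details) at each ultrasound train onset. VO2 is proportional to H; the
#' respiratory quotient relaxes with time constant `rq_tau` toward a target
#' that interpolates from `rq_normal` to `rq_torpid` as H falls (substrate
#' switching toward fat oxidation is much slower than the drop in oxygen
#' consumption, so the RQ minimum trails the VO2 minimum by tens of minutes),
#' and VCO2 = RQ(t) * VO2. The BAT surface temperature is a quasi-steady
#' proxy `T_core + bat_offset + bat_gain * (H - H0)`.
#'
#' Defaults are tuned so that a single 6-stimulus train at 1.6 MPa produces a
#' core-temperature dip of roughly 3 degC with spontaneous recovery over about
#' an hour at 22 degC ambient, the phenomenology of a torpor-like bout.
#'
#' @param t_amb ambient temperature, degC
#' @param k_loss heat-loss rate constant, 1/min (> 0)
#' @param k_therm thermogenic gain at full drive, degC/min (> 0)
#' @param h0 baseline thermogenic drive, in [0, 1]
#' @param suppression_per_train drive decrement per stimulus train at full
#'   pressure, in [0, 1]
#' @param h_floor lower bound on the drive: suppression saturates here, so
#'   repeated trains cannot push thermogenesis below this level; the default
#'   equals `h0 - suppression_per_train`, i.e. one full-pressure train from
#'   baseline already reaches the floor
#' @param tau_recovery drive recovery time constant, min (> 0)
#' @param noise_sd temperature measurement noise SD, degC (>= 0)
#' @param vo2_basal basal (non-thermogenic) oxygen consumption, ml/min
#' @param vo2_gain oxygen consumption per unit drive, ml/min
#' @param vo2_noise_sd VO2 measurement noise SD, ml/min
#' @param rq_normal,rq_torpid respiratory quotient at baseline and in deep
#'   suppression, each in [0.6, 1.1]
#' @param rq_tau relaxation time of the respiratory quotient toward its
#'   drive-dependent target, min
#' @param rq_drive_floor fraction of baseline drive below which the RQ
#'   target saturates at `rq_torpid`
#' @param bat_offset BAT surface minus core temperature at baseline drive, degC
#' @param bat_gain BAT surface sensitivity to drive deviation, degC per unit H
#' @param pressure_threshold_mpa acoustic pressure below which a train has no
#'   suppressive effect (dose-response threshold)
#' @param pressure_full_mpa pressure at which `suppression_per_train` applies
#'   in full; suppression scales linearly between threshold and this value and
#'   proportionally above it
#' @return a validated list of class `plant_params`
#' @export
#' @examples
#' p <- plant_params()
#' plant_equilibrium(p)
plant_params <- function(t_amb = 22,
                         k_loss = 0.035,
                         k_therm = 0.6475,
                         h0 = 0.8,
                         suppression_per_train = 0.45,
                         h_floor = 0.35,
                         tau_recovery = 32,
                         noise_sd = 0.05,
                         vo2_basal = 1.29,
                         vo2_gain = 3.0,
                         vo2_noise_sd = 0.05,
                         rq_normal = 0.85,
                         rq_torpid = 0.72,
                         rq_tau = 25,
                         rq_drive_floor = 0.9,
                         bat_offset = -1.5,
                         bat_gain = 2.0,
                         pressure_threshold_mpa = 0.8,
                         pressure_full_mpa = 1.6) {
  assert_number(t_amb, "t_amb", -20, 45)
  assert_number(k_loss, "k_loss", 0, strict_lower = TRUE)
  assert_number(k_therm, "k_therm", 0, strict_lower = TRUE)
  assert_number(h0, "h0", 0, 1)
  assert_number(suppression_per_train, "suppression_per_train", 0, 1)
  assert_number(h_floor, "h_floor", 0, h0)
  assert_number(tau_recovery, "tau_recovery", 0, strict_lower = TRUE)
  assert_number(noise_sd, "noise_sd", 0)
  assert_number(vo2_basal, "vo2_basal", 0)
  assert_number(vo2_gain, "vo2_gain", 0)
  assert_number(vo2_noise_sd, "vo2_noise_sd", 0)
  assert_number(rq_normal, "rq_normal", 0.6, 1.1)
  assert_number(rq_torpid, "rq_torpid", 0.6, 1.1)
  assert_number(rq_tau, "rq_tau", 0, strict_lower = TRUE)
  assert_number(rq_drive_floor, "rq_drive_floor", 0, 0.99)
  assert_number(bat_offset, "bat_offset", -10, 10)
  assert_number(bat_gain, "bat_gain", 0, 20)
  assert_number(pressure_threshold_mpa, "pressure_threshold_mpa", 0)
  assert_number(pressure_full_mpa, "pressure_full_mpa",
                pressure_threshold_mpa, strict_lower = TRUE)
  structure(list(
    t_amb = t_amb, k_loss = k_loss, k_therm = k_therm, h0 = h0,
    suppression_per_train = suppression_per_train, h_floor = h_floor,
    tau_recovery = tau_recovery, noise_sd = noise_sd,
    vo2_basal = vo2_basal, vo2_gain = vo2_gain,
    vo2_noise_sd = vo2_noise_sd,
    rq_normal = rq_normal, rq_torpid = rq_torpid, rq_tau = rq_tau,
    rq_drive_floor = rq_drive_floor,
    bat_offset = bat_offset, bat_gain = bat_gain,
    pressure_threshold_mpa = pressure_threshold_mpa,
    pressure_full_mpa = pressure_full_mpa
  ), class = "plant_params")
}

#' @rdname plant_params
#' @param params a `plant_params` object
#' @export
plant_equilibrium <- function(params) {
  params$t_amb + params$k_therm * params$h0 / params$k_loss
}

# Dose scaling of the per-train drive decrement: zero below the pressure
# threshold, linear through (threshold, 0) -> (full, 1), proportional above.
pressure_scale <- function(params, pressure_mpa) {
  pmax(0, (pressure_mpa - params$pressure_threshold_mpa) /
         (params$pressure_full_mpa - params$pressure_threshold_mpa))
}

# Single explicit-Euler step of the deterministic plant state.
# state: list(T = core temp, H = drive). Returns the advanced state.
plant_step <- function(state, params, dt_min) {
  dT <- -params$k_loss * (state$T - params$t_amb) + params$k_therm * state$H
  dH <- (params$h0 - state$H) / params$tau_recovery
  list(T = state$T + dt_min * dT, H = state$H + dt_min * dH)
}

plant_apply_train <- function(state, params, pressure_mpa) {
  dec <- params$suppression_per_train * pressure_scale(params, pressure_mpa)
  state$H <- max(params$h_floor, state$H - dec)
  state
}

# Drive-dependent RQ target, and its lagged realization over a drive series.
# Below `rq_drive_floor` of baseline drive the target saturates at the torpid
# (fat-oxidation) level; above it the target rises linearly back to normal.
rq_target <- function(params, Hv) {
  frac <- pmin(1, pmax(0, (Hv / params$h0 - params$rq_drive_floor) /
                         (1 - params$rq_drive_floor)))
  params$rq_torpid + (params$rq_normal - params$rq_torpid) * frac
}

rq_lagged <- function(params, Hv, dt_min) {
  target <- rq_target(params, Hv)
  rq <- numeric(length(Hv))
  rq[1] <- target[1]
  if (length(Hv) > 1) {
    for (i in 2:length(Hv)) {
      rq[i] <- rq[i - 1] + dt_min * (target[i] - rq[i - 1]) / params$rq_tau
    }
  }
  rq
}

# Observation model for simulate_plant.
plant_observe <- function(Tv, Hv, rq, params, noise) {
  vo2 <- params$vo2_basal + params$vo2_gain * Hv + noise$vo2
  list(
    t_core = Tv + noise$t_core,
    t_bat = Tv + params$bat_offset + params$bat_gain * (Hv - params$h0) +
      noise$t_bat,
    vo2 = vo2,
    vco2 = rq * vo2
  )
}

#' Simulate the thermoregulatory plant under a stimulus schedule
#'
#' Integrates the plant ODE (explicit Euler) over `duration_min` minutes,
#' applying one drive decrement at the onset of each stimulus train in
#' `schedule`, and returns the observed physiology with measurement noise.
#'
#' @param params a [plant_params()] object
#' @param schedule a stimulus schedule tibble with columns `onset_s`,
#'   `offset_s`, `pressure_mpa` and optionally `train_id` (events sharing a
#'   `train_id` form one train and trigger one decrement at the first onset;
#'   without `train_id` every row counts as its own train), or `NULL` for an
#'   unstimulated run
#' @param duration_min total simulated time, min
#' @param dt_min integration step, min (default 0.05; keep <= 0.1)
#' @param t0 initial core temperature, degC; default the plant equilibrium
#' @param seed integer seed; the run is a pure function of (params, schedule,
#'   seed)
#' @return a tibble of class `plant_sim` with columns `time_s`, `t_core`,
#'   `t_bat`, `vo2`, `vco2`, `rq`, `drive`; attributes `params`, `schedule`,
#'   `seed`
#' @export
#' @examples
#' sim <- simulate_plant(plant_params(noise_sd = 0), NULL, duration_min = 30)
#' range(sim$t_core)
simulate_plant <- function(params, schedule = NULL, duration_min,
                           dt_min = 0.05, t0 = NULL, seed = 1L) {
  stopifnot(inherits(params, "plant_params"))
  assert_number(dt_min, "dt_min", 0, strict_lower = TRUE)
  assert_number(duration_min, "duration_min", dt_min)
  n <- floor(duration_min / dt_min) + 1L
  times_min <- (seq_len(n) - 1L) * dt_min

  train_onsets <- numeric(0)
  train_pressure <- numeric(0)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    sch <- as.data.frame(schedule)
    if (!"train_id" %in% names(sch)) sch$train_id <- seq_len(nrow(sch))
    first <- !duplicated(sch$train_id)
    train_onsets <- sch$onset_s[first] / 60
    train_pressure <- if ("pressure_mpa" %in% names(sch)) {
      sch$pressure_mpa[first]
    } else {
      rep(params$pressure_full_mpa, sum(first))
    }
    ord <- order(train_onsets)
    train_onsets <- train_onsets[ord]
    train_pressure <- train_pressure[ord]
  }

  state <- list(T = t0 %||% plant_equilibrium(params), H = params$h0)
  Tv <- numeric(n)
  Hv <- numeric(n)
  next_train <- 1L
  for (i in seq_len(n)) {
    t_min <- times_min[i]
    while (next_train <= length(train_onsets) &&
           train_onsets[next_train] <= t_min + 1e-9) {
      state <- plant_apply_train(state, params, train_pressure[next_train])
      next_train <- next_train + 1L
    }
    Tv[i] <- state$T
    Hv[i] <- state$H
    state <- plant_step(state, params, dt_min)
  }

  set.seed(derive_seed(seed))
  noise <- list(
    t_core = rnorm(n, 0, params$noise_sd),
    t_bat = rnorm(n, 0, params$noise_sd),
    vo2 = rnorm(n, 0, params$vo2_noise_sd)
  )
  obs <- plant_observe(Tv, Hv, rq_lagged(params, Hv, dt_min), params, noise)
  out <- tibble::tibble(
    time_s = times_min * 60,
    t_core = obs$t_core, t_bat = obs$t_bat,
    vo2 = obs$vo2, vco2 = obs$vco2,
    rq = ifelse(obs$vo2 > 0, obs$vco2 / obs$vo2, NA_real_),
    drive = Hv
  )
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "seed") <- seed
  class(out) <- c("plant_sim", class(out))
  out
}

#' @rdname simulate_plant
#' @param x a `plant_sim`
#' @param signal which column to extract
#' @param unit unit tag for the resulting trace
#' @export
plant_trace <- function(x, signal = c("t_core", "t_bat", "vo2", "vco2", "rq"),
                        unit = NULL) {
  signal <- match.arg(signal)
  default_units <- c(t_core = "degC", t_bat = "degC", vo2 = "ml_per_min",
                     vco2 = "ml_per_min", rq = "ratio")
  new_trace(x$time_s, x[[signal]], unit %||% default_units[[signal]])
}
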