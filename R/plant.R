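# Surrogate robot plant: first-order servo tracking of the commanded joint
# angle plus a linear elastic fingertip contact model.

#' Robot plant configuration
#'
#' The tendon-driven finger and its PID joint controller are surrogated by
#' critically damped first-order tracking of the commanded angle with time
#' constant `tau_ms`. Fingertip contact occurs above `theta_c` and produces a
#' steady force `F_DC = stiffness * (theta - theta_c)` (contact units) plus
#' sensor noise; the dynamic channel `F_AC` is the discrete derivative of a
#' lightly smoothed `F_DC`.
#'
#' @param tau_ms servo time constant toward higher commanded angles (ms).
#' @param release_tau_ms servo time constant on release (ms); tendon-driven
#'   fingers extend slower than they flex, which keeps the fingertip force
#'   smooth between consecutive tap commands.
#' @param deadband_deg viscoelastic backlash of the fingertip contact (deg):
#'   joint flutter smaller than this does not modulate the sensed force, so
#'   only genuine contact transients reach the dynamic force channel.
#' @param theta_c contact angle (deg); must lie strictly between the decoder's
#'   open and contact angles.
#' @param stiffness contact stiffness (contact units per deg).
#' @param sensor_noise_sd force sensor noise SD (contact units).
#' @param control_rate control loop rate (Hz).
#' @param smooth_samples moving-average window (samples) applied to `F_DC`
#'   before differentiation.
#' @return object of class `plant_config`.
#' @export
plant_config <- function(tau_ms = 30, release_tau_ms = 1000, theta_c = 15,
                         deadband_deg = 4, stiffness = 0.006,
                         sensor_noise_sd = 5e-04, control_rate = 1000,
                         smooth_samples = 25) {
  stopifnot(tau_ms > 0, release_tau_ms > 0, deadband_deg >= 0, stiffness >= 0,
            control_rate > 0)
  structure(list(tau_ms = tau_ms, release_tau_ms = release_tau_ms,
                 theta_c = theta_c, deadband_deg = deadband_deg,
                 stiffness = stiffness,
                 sensor_noise_sd = sensor_noise_sd,
                 control_rate = control_rate, smooth_samples = smooth_samples),
            class = "plant_config")
}

#' Advance the joint one control tick
#'
#' Exact discretization of first-order relaxation toward the commanded angle:
#' `theta' = theta_d + (theta - theta_d) * exp(-dt / tau)`.
#'
#' @param theta_d commanded angle (deg).
#' @param theta current measured angle (deg).
#' @param config a [plant_config()].
#' @return list with `theta` (new angle) and `in_contact` (logical).
#' @export
step_plant <- function(theta_d, theta, config = plant_config()) {
  tau <- if (theta_d >= theta) config$tau_ms else config$release_tau_ms
  alpha <- exp(-(1000 / config$control_rate) / tau)
  theta_new <- theta_d + (theta - theta_d) * alpha
  list(theta = theta_new, in_contact = theta_new >= config$theta_c)
}

#' Track a command timeline
#'
#' Vector form of [step_plant()] over a whole commanded-angle timeline.
#'
#' @param theta_d commanded angle timeline (deg) at the control rate.
#' @param theta0 initial angle (deg).
#' @param config a [plant_config()].
#' @return numeric vector of measured angles, same length as `theta_d`.
#' @export
run_plant <- function(theta_d, theta0 = NULL, config = plant_config()) {
  theta0 <- theta0 %||% theta_d[1]
  n <- length(theta_d)
  out <- numeric(n)
  th <- theta0
  for (t in seq_len(n)) {
    th <- step_plant(theta_d[t], th, config)$theta
    out[t] <- th
  }
  out
}

#' Fingertip force streams from a joint trajectory
#'
#' Elastic contact: `F_DC = stiffness * max(0, theta - theta_c)` plus sensor
#' noise while in contact (clamped at zero). `F_AC` is the 3-sample centered
#' difference of the moving-average-smoothed `F_DC`. Out of contact both
#' channels are exactly zero (`F_AC` up to the smoothing support of contact
#' edges).
#'
#' @param theta measured joint-angle trajectory (deg) at the control rate.
#' @param config a [plant_config()].
#' @param seed optional seed for the sensor noise; `NULL` uses the current
#'   RNG stream.
#' @return object of class `force_signal`: list with `f_dc`, `f_ac`,
#'   `timestamps` (s) and `rate` (Hz).
#' @export
sense_forces <- function(theta, config = plant_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta)
  dt <- 1 / config$control_rate
  theta_eff <- backlash_filter(theta, config$deadband_deg)
  pen <- pmax(0, theta_eff - config$theta_c)
  f_dc <- config$stiffness * pen
  in_contact <- pen > 0
  if (config$sensor_noise_sd > 0 && any(in_contact)) {
    f_dc[in_contact] <- pmax(0, f_dc[in_contact] +
                               rnorm(sum(in_contact), 0, config$sensor_noise_sd))
  }
  fs_smooth <- moving_average(f_dc, config$smooth_samples)
  f_ac <- c(0, (fs_smooth[-(1:2)] - fs_smooth[1:(n - 2)]) / (2 * dt), 0)
  structure(list(f_dc = f_dc, f_ac = f_ac,
                 timestamps = (seq_len(n) - 1) * dt,
                 rate = config$control_rate),
            class = "force_signal")
}

#' Efferent-substitution command waveform
#'
#' The fixed 0.25 Hz square wave that drives the finger in ES sessions:
#' 2 s at the contact angle, 2 s at the open angle (period 4 s, 50% duty),
#' starting out of contact at t = 0.
#'
#' @param t time (s), vectorized.
#' @param theta1 open-hand angle (deg).
#' @param theta2 contact angle (deg).
#' @param freq fundamental frequency (Hz), default 0.25.
#' @return commanded angle at each `t`.
#' @export
es_waveform <- function(t, theta1 = 0, theta2 = 45, freq = 0.25) {
  stopifnot(all(t >= 0))
  phase <- (t * freq) %% 1
  ifelse(phase < 0.5, theta1, theta2)
}


#' Backlash (hysteresis) filter
#'
#' Classic backlash operator with half-width `deadband`: the output follows
#' the input only once it escapes the deadband around the current output.
#'
#' @param x numeric series.
#' @param deadband half-width of the deadband (same units as `x`).
#' @return filtered series, same length.
#' @export
backlash_filter <- function(x, deadband) {
  if (deadband <= 0 || length(x) == 0) return(x)
  out <- numeric(length(x))
  y <- x[1]
  for (i in seq_along(x)) {
    if (x[i] - y > deadband) y <- x[i] - deadband
    else if (y - x[i] > deadband) y <- x[i] + deadband
    out[i] <- y
  }
  out
}
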