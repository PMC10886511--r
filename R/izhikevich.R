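# SA/RA mechanoreceptor encoding of fingertip forces via the Izhikevich model.

#' Izhikevich neuron parameters
#'
#' Parameters of the two-variable Izhikevich model used as the mechanoreceptor
#' encoder: \eqn{\dot v = Xv^2 + Yv + Z + I - u}, \eqn{\dot u = a(bv - u)},
#' with reset \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d} when
#' \eqn{v \ge 30} mV. Defaults are the regular-spiking parameterization used
#' for tactile encoding (a = 0.1, b = 0.2, c = -65 mV, d = 8; membrane
#' polynomial 0.04, 5, 140).
#'
#' @param a recovery decay rate (1/ms scale).
#' @param b recovery sensitivity to `v`.
#' @param c reset potential (mV); must be below the 30 mV spike cutoff.
#' @param d recovery increment at reset.
#' @param X,Y,Z membrane polynomial coefficients.
#' @param dt forward-Euler integration step (ms); must be positive.
#' @return object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.1, b = 0.2, c = -65, d = 8,
                              X = 0.04, Y = 5, Z = 140, dt = 0.5) {
  stopifnot(dt > 0, c < 30)
  structure(list(a = a, b = b, c = c, d = d, X = X, Y = Y, Z = Z, dt = dt),
            class = "izhikevich_params")
}

#' Encoder input-current gains
#'
#' Gains mapping the steady (`F_DC`) and dynamic (`F_AC`) fingertip force
#' channels to the encoder neuron's input current:
#' SA current = `beta + k_sa * F_DC + k_ra * F_AC`;
#' RA current = `alpha + k_ra * F_AC`.
#' Defaults are chosen so that, with the default plant, the SA encoder fires
#' tonically at a few tens of Hz during sustained contact while the RA encoder
#' emits a handful of spikes at each contact edge.
#'
#' @param alpha RA baseline current.
#' @param beta SA baseline current.
#' @param k_sa current per unit steady force (must be >= 0).
#' @param k_ra current per unit dynamic force (must be >= 0).
#' @return object of class `encoder_gains`.
#' @export
encoder_gains <- function(alpha = 2, beta = 3, k_sa = 20, k_ra = 8) {
  stopifnot(k_sa >= 0, k_ra >= 0)
  structure(list(alpha = alpha, beta = beta, k_sa = k_sa, k_ra = k_ra),
            class = "encoder_gains")
}

#' Encoder neuron state
#'
#' Membrane potential `v` (mV) and recovery variable `u`. The default is the
#' resting fixed point of the default parameters (v = -70 mV, u = b*v).
#'
#' @param v membrane potential (mV).
#' @param u recovery variable.
#' @return object of class `neuron_state`.
#' @export
neuron_state <- function(v = -70, u = -14) {
  stopifnot(is.finite(v), is.finite(u))
  structure(list(v = v, u = u), class = "neuron_state")
}

#' Resting fixed point of the Izhikevich model
#'
#' Solves \eqn{Xv^2 + (Y - b)v + Z = 0} for the stable (more hyperpolarized)
#' root and returns the corresponding state with `u = b * v`. Errors if no
#' real rest state exists (suprathreshold bias).
#'
#' @param params an [izhikevich_params()] object.
#' @param I constant bias current included in the balance (default 0).
#' @return a [neuron_state()] at the resting equilibrium.
#' @export
izhikevich_fixed_point <- function(params = izhikevich_params(), I = 0) {
  disc <- (params$Y - params$b)^2 - 4 * params$X * (params$Z + I)
  if (disc < 0) stop("no resting equilibrium for this bias current", call. = FALSE)
  v <- (-(params$Y - params$b) - sqrt(disc)) / (2 * params$X)
  neuron_state(v = v, u = params$b * v)
}

#' Mechanoreceptor input current
#'
#' Affine map from the fingertip force channels to the encoder neuron current.
#' In SA mode the current depends on both the steady force and the dynamic
#' channel; in RA mode it depends solely on the dynamic channel, so it is
#' invariant to `f_dc`.
#'
#' @param f_dc steady fingertip force (contact units, >= 0); vectorized.
#' @param f_ac dynamic force channel (contact units/s); vectorized.
#' @param gains an [encoder_gains()] object.
#' @param mode `"SA"` or `"RA"`.
#' @return input current in model units (same length as the force vectors).
#' @export
compute_input_current <- function(f_dc, f_ac, gains = encoder_gains(),
                                  mode = c("SA", "RA")) {
  mode <- match.arg(mode)
  if (!all(is.finite(f_dc)) || !all(is.finite(f_ac)))
    stop("rejected input signal: non-finite force sample", call. = FALSE)
  if (any(f_dc < 0)) stop("rejected input signal: negative steady force", call. = FALSE)
  if (mode == "SA") gains$beta + gains$k_sa * f_dc + gains$k_ra * f_ac
  else gains$alpha + gains$k_ra * f_ac
}

#' Advance the encoder neuron by one step
#'
#' One forward-Euler step of the Izhikevich model followed by the reset rule:
#' if `v >= 30` mV the neuron spikes, `v <- c`, `u <- u + d`, and the
#' stimulation trigger line is raised to 4.5 V (0 V otherwise).
#'
#' @param state a [neuron_state()].
#' @param I input current (model units).
#' @param params an [izhikevich_params()].
#' @return list with `state` (new [neuron_state()]), `spiked` (logical) and
#'   `trigger_level` (volts, 4.5 at a spike, 0 otherwise).
#' @export
step_neuron <- function(state, I, params = izhikevich_params()) {
  dt <- params$dt
  v <- state$v + dt * (params$X * state$v^2 + params$Y * state$v + params$Z +
                         I - state$u)
  u <- state$u + dt * params$a * (params$b * state$v - state$u)
  if (!is.finite(v) || abs(v) > 1e6) {
    stop("numerical instability in Izhikevich integration at dt = ", dt,
         " ms; reduce dt", call. = FALSE)
  }
  if (v >= 30) {
    list(state = neuron_state(v = params$c, u = u + params$d),
         spiked = TRUE, trigger_level = 4.5)
  } else {
    list(state = neuron_state(v = v, u = u), spiked = FALSE, trigger_level = 0)
  }
}

#' Stimulation trigger train
#'
#' Times at which the encoder emitted a 4.5 V stimulation trigger, with the
#' encoding label attached. Times must be strictly increasing.
#'
#' @param spike_times trigger times (s).
#' @param encoding `"SA"` or `"RA"`.
#' @param trigger_level trigger level at spikes (V); 4.5 by construction.
#' @return object of class `stim_trigger_train`.
#' @export
stim_trigger_train <- function(spike_times = numeric(0),
                               encoding = c("SA", "RA"),
                               trigger_level = 4.5) {
  encoding <- match.arg(encoding)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop("trigger times must be strictly increasing", call. = FALSE)
  if (!trigger_level %in% c(0, 4.5))
    stop("trigger level must be 0 or 4.5 V", call. = FALSE)
  structure(list(spike_times = spike_times, encoding = encoding,
                 trigger_level = trigger_level),
            class = "stim_trigger_train")
}

#' @export
print.stim_trigger_train <- function(x, ...) {
  cat(sprintf("<stim_trigger_train> %s encoding, %d triggers at %.1f V\n",
              x$encoding, length(x$spike_times), x$trigger_level))
  invisible(x)
}

#' @export
length.stim_trigger_train <- function(x) length(x$spike_times)

#' Encode a force stream into a stimulation trigger train
#'
#' Runs the Izhikevich mechanoreceptor encoder sample by sample over a
#' fingertip force stream sampled at a fixed control rate. Between force
#' samples the neuron is integrated with `round(1000 / rate / params$dt)`
#' Euler substeps so the model step `dt` is honored regardless of the control
#' rate. SA mode fires tonically during sustained contact; RA mode fires only
#' while the dynamic channel is large.
#'
#' @param f_dc steady force samples (contact units).
#' @param f_ac dynamic force channel samples (contact units/s); pass the
#'   rectified derivative for the sensor's vibration-magnitude channel.
#' @param rate control rate (Hz) at which the forces are sampled.
#' @param mode `"SA"` or `"RA"`.
#' @param gains an [encoder_gains()].
#' @param params an [izhikevich_params()].
#' @param state0 initial [neuron_state()]; defaults to the resting point.
#' @return a [stim_trigger_train()] with trigger times in seconds.
#' @export
encode_force_stream <- function(f_dc, f_ac, rate = 1000,
                                mode = c("SA", "RA"),
                                gains = encoder_gains(),
                                params = izhikevich_params(),
                                state0 = NULL) {
  mode <- match.arg(mode)
  n <- length(f_dc)
  stopifnot(length(f_ac) == n)
  if (n == 0) return(stim_trigger_train(numeric(0), encoding = mode))
  I <- compute_input_current(f_dc, f_ac, gains, mode)
  substeps <- max(1L, as.integer(round(1000 / rate / params$dt)))
  st <- state0 %||% izhikevich_fixed_point(params)
  times <- cpp_encode_stream(I, st$v, st$u, params$a, params$b, params$c,
                             params$d, params$X, params$Y, params$Z,
                             params$dt, substeps)
  # at most one trigger is emitted per control tick
  stim_trigger_train((times - 1) / rate, encoding = mode)
}

#' Render a charge-balanced biphasic stimulation pulse
#'
#' Positive-first rectangular biphasic waveform delivered at each trigger.
#' Triggers closer together than one full pulse width are merged by a
#' refractory rule: the earlier trigger wins and later ones inside its pulse
#' are suppressed.
#'
#' @param trigger_times trigger times (s), sorted.
#' @param fs sampling rate of the rendered waveform (Hz).
#' @param amplitude phase amplitude (uV at the electrode).
#' @param phase_ms duration of each phase (ms).
#' @param duration total waveform duration (s); defaults to just past the
#'   last pulse.
#' @return list with `waveform` (numeric vector), `fs`, `kept_times` (the
#'   triggers actually rendered) and `suppressed_times`.
#' @export
render_biphasic_pulse <- function(trigger_times, fs = 20000, amplitude = 200,
                                  phase_ms = 0.5, duration = NULL) {
  trigger_times <- sort(as.numeric(trigger_times))
  pulse_width <- 2 * phase_ms / 1000
  keep <- enforce_min_separation(trigger_times, pulse_width)
  kept <- trigger_times[keep]
  duration <- duration %||% (if (length(kept)) max(kept) + 2 * pulse_width else pulse_width)
  wave <- numeric(ceiling(duration * fs))
  w <- max(1L, round(phase_ms / 1000 * fs))
  for (t in kept) {
    i0 <- floor(t * fs) + 1L
    i1 <- min(i0 + w - 1L, length(wave))
    i2 <- min(i0 + 2L * w - 1L, length(wave))
    if (i0 <= length(wave)) wave[i0:i1] <- wave[i0:i1] + amplitude
    if (i1 + 1L <= i2) wave[(i1 + 1L):i2] <- wave[(i1 + 1L):i2] - amplitude
  }
  list(waveform = wave, fs = fs, kept_times = kept,
       suppressed_times = trigger_times[!keep])
}

#' Enforce a minimum separation between event times
#'
#' Greedy left-to-right rule: an event is kept iff it is at least `min_sep`
#' after the last kept event ("earlier trigger wins").
#'
#' @param times sorted event times.
#' @param min_sep minimum separation (same units as `times`).
#' @return logical vector marking kept events.
#' @export
enforce_min_separation <- function(times, min_sep) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= min_sep) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}
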