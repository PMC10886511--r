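# Surrogate for the cultured network on the 60-electrode MEA: a recurrent
# Izhikevich network with short-term synaptic depression and slow
# spike-frequency adaptation, plus extracellular trace synthesis.

#' MEA electrode layout
#'
#' The standard 60-site layout: an 8 x 8 grid with the four corners removed,
#' 200 um pitch, 30 um electrode diameter.
#'
#' @param pitch_um inter-electrode distance (um).
#' @return data.frame with `electrode`, `row`, `col`, `x_um`, `y_um`.
#' @export
mea_layout <- function(pitch_um = 200) {
  g <- expand.grid(row = 1:8, col = 1:8)
  corners <- (g$row %in% c(1, 8)) & (g$col %in% c(1, 8))
  g <- g[!corners, ]
  g <- g[order(g$col, g$row), ]
  data.frame(electrode = seq_len(nrow(g)), row = g$row, col = g$col,
             x_um = (g$col - 1) * pitch_um, y_um = (g$row - 1) * pitch_um)
}

#' Neighboring electrodes
#'
#' The up-to-8 electrodes adjacent (including diagonals) to a site on the
#' grid.
#'
#' @param electrode electrode id.
#' @param layout layout from [mea_layout()].
#' @return integer vector of neighbor electrode ids.
#' @export
mea_neighbors <- function(electrode, layout = mea_layout()) {
  e <- layout[layout$electrode == electrode, ]
  nb <- layout[abs(layout$row - e$row) <= 1 & abs(layout$col - e$col) <= 1 &
                 layout$electrode != electrode, ]
  nb$electrode
}

#' Culture surrogate configuration
#'
#' Parameters of the Izhikevich-network stand-in for the cultured network.
#' The defaults produce spontaneous population bursts (via recurrent
#' excitation limited by short-term depression), stimulation-evoked responses
#' near the afferent electrode, and slow spike-frequency adaptation through
#' which sustained afferent stimulation transiently lowers network
#' excitability. None of these parameters claims biological fidelity; they
#' are the knobs of a qualitative surrogate.
#'
#' @param n_neurons network size (default 400; 80% excitatory).
#' @param frac_inhibitory fraction of fast-spiking inhibitory neurons.
#' @param connection_probability sparse random connectivity probability.
#' @param w_exc,w_inh synaptic weight scales (peak current per presynaptic
#'   spike).
#' @param tau_syn synaptic current decay time constant (ms); exponential
#'   synapses let recurrent activity reverberate into population bursts of
#'   the 100 ms-1 s durations seen in dissociated cultures.
#' @param drive_exc,drive_inh per-substep background current SD for
#'   excitatory / inhibitory neurons (thalamic-style noise drive).
#' @param depression_u release fraction of short-term synaptic depression.
#' @param depression_tau recovery time constant of depression (ms).
#' @param adaptation_inc slow adaptation current increment per spike.
#' @param adaptation_tau slow adaptation decay time constant (ms).
#' @param stim_gain stimulation current amplitude at the afferent site.
#' @param stim_lambda_um length constant of stimulation current spread (um).
#' @param stim_radius_um neurons beyond this distance receive no stimulation.
#' @param afferent_exclusion_um no neurons are placed within this distance
#'   of the stimulation electrode: the protocol selects a stimulation site
#'   whose recorded signal is artifact rather than local units, so its
#'   spontaneous trace is noise and crosstalk verification is clean.
#'   Stimulation still recruits the units in the surrounding annulus.
#' @param stim_dep_u release fraction of the stimulation-pathway short-term
#'   depression (per delivered pulse).
#' @param stim_dep_tau recovery time constant of the stimulation pathway (ms).
#' @param pathway_gain per-pulse drive (fraction of `stim_gain`) reaching
#'   the efferent-site neurons through the selected synaptic pathway between
#'   the stimulation and recording sites; shares the stimulation-pathway
#'   depression.
#' @param stim_adapt_rise rise time constant (ms) of the suppression; the
#'   charge delivered during a tap feeds the slow suppression current through
#'   this cascade, so suppression peaks after the tap ends and gates the
#'   initiation of the next burst rather than truncating the ongoing one.
#' @param stim_adapt slow network suppression accrued per delivered pulse
#'   (scaled by the pathway resource); decays with `adaptation_tau`. This is
#'   the surrogate's sensorimotor-specialization dial: sustained (SA-like)
#'   stimulation suppresses network excitability for longer than transient
#'   (RA-like) stimulation, lengthening subsequent inter-tap intervals.
#' @param capture_radius_um neurons within this distance of an electrode are
#'   recorded strongly by it.
#' @param n_seed_efferent,n_seed_afferent neurons placed deterministically
#'   near the chosen efferent / afferent sites (the wet-lab protocol selects
#'   a recording site with healthy activity; by default no units sit at the
#'   stimulation site itself).
#' @param efferent_electrode,afferent_electrode electrode ids of the
#'   recording and stimulation sites.
#' @param noise_rms extracellular noise floor (uV), within the 10-20 uV
#'   acceptance band of the recording system.
#' @param fs extracellular sampling rate (Hz), 20 kHz by default.
#' @param amp_range spike template peak amplitude range at the home
#'   electrode (uV).
#' @param amp_lambda_um spatial attenuation length of spike amplitude (um).
#' @param artifact_amp stimulation artifact amplitude at the afferent
#'   electrode (uV).
#' @param crosstalk_gain fraction of the artifact amplitude reaching the
#'   8 neighboring electrodes through the medium.
#' @param saturation_uv recording-chain saturation (uV): traces are clipped
#'   to this range, as a real amplifier/ADC front end would; this also keeps
#'   the global power maximum (the reference for the envelope clip band)
#'   stable across sessions instead of tracking rare coincident-spike
#'   outliers.
#' @return object of class `culture_config`.
#' @export
culture_config <- function(n_neurons = 400, frac_inhibitory = 0.2,
                           connection_probability = 0.1,
                           w_exc = 2.5, w_inh = -2, tau_syn = 20,
                           drive_exc = 4.5, drive_inh = 1.8,
                           depression_u = 0.15, depression_tau = 1200,
                           adaptation_inc = 0.06, adaptation_tau = 4000,
                           stim_gain = 80, stim_lambda_um = 200,
                           stim_radius_um = 250,
                           afferent_exclusion_um = 185,
                           stim_dep_u = 0.15, stim_dep_tau = 150,
                           stim_adapt = 0.035, stim_adapt_rise = 600,
                           pathway_gain = 0.2,
                           capture_radius_um = 60,
                           n_seed_efferent = 10, n_seed_afferent = 0,
                           efferent_electrode = 28, afferent_electrode = 33,
                           noise_rms = 15, fs = 20000,
                           amp_range = c(150, 180), amp_lambda_um = 40,
                           artifact_amp = 200, crosstalk_gain = 0.2,
                           saturation_uv = 220) {
  stopifnot(n_neurons >= 10, frac_inhibitory > 0, frac_inhibitory < 1,
            noise_rms > 0, fs > 0,
            efferent_electrode != afferent_electrode)
  if (noise_rms < 10 || noise_rms > 20)
    warning("noise_rms outside the 10-20 uV acceptance band of the recording chain",
            call. = FALSE)
  structure(as.list(environment()), class = "culture_config")
}

#' Instantiate a culture surrogate
#'
#' Draws neuron positions, types, Izhikevich parameters and sparse random
#' connectivity under the given seed. A handful of neurons are placed near
#' the designated efferent and afferent electrodes so both sites record
#' healthy activity, mirroring the electrode-selection step of the recording
#' protocol.
#'
#' @param config a [culture_config()].
#' @param seed integer seed (required: cultures are reproducible objects).
#' @return object of class `culture`: neuron table, connectivity in
#'   compressed form, layout, and electrode assignment.
#' @export
build_culture <- function(config = culture_config(), seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required to build a culture (reproducibility contract)",
         call. = FALSE)
  set.seed(seed)
  n <- config$n_neurons
  layout <- mea_layout()
  span <- c(min(layout$x_um), max(layout$x_um))
  x <- runif(n, span[1] - 100, span[2] + 100)
  y <- runif(n, span[1] - 100, span[2] + 100)

  n_inh <- round(config$frac_inhibitory * n)
  is_exc <- c(rep(TRUE, n - n_inh), rep(FALSE, n_inh))

  # pin a few excitatory neurons near the chosen recording/stimulation sites
  eff <- layout[layout$electrode == config$efferent_electrode, ]
  aff <- layout[layout$electrode == config$afferent_electrode, ]
  k1 <- seq_len(config$n_seed_efferent)
  k2 <- if (config$n_seed_afferent > 0)
    config$n_seed_efferent + seq_len(config$n_seed_afferent) else integer(0)
  r1 <- runif(length(k1), 0, 0.35 * config$capture_radius_um)
  a1 <- runif(length(k1), 0, 2 * pi)
  x[k1] <- eff$x_um + r1 * cos(a1); y[k1] <- eff$y_um + r1 * sin(a1)
  if (length(k2)) {
    r2 <- runif(length(k2), 0, 0.6 * config$capture_radius_um)
    a2 <- runif(length(k2), 0, 2 * pi)
    x[k2] <- aff$x_um + r2 * cos(a2); y[k2] <- aff$y_um + r2 * sin(a2)
  }
  # keep the stimulation site itself free of units
  if (config$afferent_exclusion_um > 0) {
    relocate <- setdiff(which(sqrt((x - aff$x_um)^2 + (y - aff$y_um)^2) <
                                config$afferent_exclusion_um), c(k1, k2))
    for (i in relocate) {
      repeat {
        xi <- runif(1, span[1] - 100, span[2] + 100)
        yi <- runif(1, span[1] - 100, span[2] + 100)
        if (sqrt((xi - aff$x_um)^2 + (yi - aff$y_um)^2) >=
              config$afferent_exclusion_um) break
      }
      x[i] <- xi; y[i] <- yi
    }
  }

  # heterogeneous Izhikevich parameters (regular-spiking / fast-spiking)
  r <- runif(n)
  a <- ifelse(is_exc, 0.02, 0.02 + 0.08 * r)
  b <- ifelse(is_exc, 0.2, 0.25 - 0.05 * r)
  cc <- ifelse(is_exc, -65 + 15 * r^2, -65)
  d <- ifelse(is_exc, 8 - 6 * r^2, 2)
  noise_sd <- ifelse(is_exc, config$drive_exc, config$drive_inh)

  # sparse random connectivity, grouped by presynaptic neuron (CSC-like)
  p <- config$connection_probability
  pre_ptr <- integer(n + 1)
  post_idx <- vector("list", n)
  wts <- vector("list", n)
  for (j in seq_len(n)) {
    tgt <- which(runif(n) < p)
    tgt <- tgt[tgt != j]
    post_idx[[j]] <- tgt - 1L
    wts[[j]] <- if (is_exc[j]) runif(length(tgt), 0, config$w_exc)
                else runif(length(tgt), config$w_inh, 0)
    pre_ptr[j + 1] <- pre_ptr[j] + length(tgt)
  }

  d_eff <- sqrt((x - eff$x_um)^2 + (y - eff$y_um)^2)
  d_aff <- sqrt((x - aff$x_um)^2 + (y - aff$y_um)^2)
  stim_coupling <- exp(-d_aff / config$stim_lambda_um)
  stim_coupling[d_aff > config$stim_radius_um] <- 0
  # functional afferent->efferent pathway: the recording protocol selects an
  # electrode pair that is synaptically connected; the surrogate models that
  # pathway as a direct per-pulse drive onto the efferent-site neurons,
  # subject to the same release depression as the stimulation pathway
  stim_coupling[k1] <- pmax(stim_coupling[k1], config$pathway_gain)

  # nearest-electrode assignment
  nearest <- integer(n)
  nearest_dist <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt((layout$x_um - x[i])^2 + (layout$y_um - y[i])^2)
    k <- which.min(dd)
    nearest[i] <- layout$electrode[k]
    nearest_dist[i] <- dd[k]
  }
  amp <- runif(n, config$amp_range[1], config$amp_range[2])

  structure(list(
    config = config, seed = seed, layout = layout,
    neurons = data.frame(
      neuron = seq_len(n), x_um = x, y_um = y, exc = is_exc,
      a = a, b = b, c = cc, d = d, noise_sd = noise_sd,
      electrode = nearest, electrode_dist_um = nearest_dist,
      amplitude_uv = amp, stim_coupling = stim_coupling,
      efferent = nearest == config$efferent_electrode &
        nearest_dist <= config$capture_radius_um),
    pre_ptr = pre_ptr,
    post_idx = unlist(post_idx, use.names = FALSE) %||% integer(0),
    weights = unlist(wts, use.names = FALSE) %||% numeric(0)
  ), class = "culture")
}

#' @export
print.culture <- function(x, ...) {
  cat(sprintf(
    "<culture> %d neurons (%d inhibitory), %d synapses, seed %d\n  efferent site %d (%d neurons), afferent site %d (%d coupled)\n",
    nrow(x$neurons), sum(!x$neurons$exc), length(x$weights), x$seed,
    x$config$efferent_electrode, sum(x$neurons$efferent),
    x$config$afferent_electrode, sum(x$neurons$stim_coupling > 0)))
  invisible(x)
}

# Stereotyped extracellular spike template (negative-first biphasic), unit
# peak magnitude, ~1.4 ms long.
spike_template <- function(fs) {
  t <- seq(0, 0.0014, by = 1 / fs)
  w <- -exp(-((t - 0.00035) / 0.00012)^2) + 0.35 * exp(-((t - 0.00075) / 0.00025)^2)
  w / max(abs(w))
}

# Positive-first biphasic stimulation artifact template, unit amplitude.
artifact_template <- function(fs, phase_ms = 0.3) {
  w <- max(1L, round(phase_ms / 1000 * fs))
  c(rep(1, w), rep(-1, w))
}

#' Synthesize extracellular traces from a spike raster
#'
#' Each spike adds the stereotyped biphasic template at its neuron's
#' amplitude, attenuated exponentially with the neuron-electrode distance;
#' Gaussian noise at the configured floor is added, stimulation artifacts
#' (and their neighbor crosstalk) are inserted, and the trace is optionally
#' band-pass filtered to mirror the online filter chain.
#'
#' @param raster data.frame with `neuron` and `time_s`.
#' @param culture a [build_culture()] object.
#' @param electrodes electrode ids to synthesize.
#' @param duration trace duration (s).
#' @param stim_times delivered stimulation times (s), or `NULL`.
#' @param band band-pass corner frequencies (Hz) of the online analogue
#'   chain, `c(100, 3500)`; `NULL` or `NA` skips filtering (the 1 Hz offline
#'   variant is approximated by the unfiltered trace).
#' @param seed optional seed for the noise.
#' @return named list of numeric traces (uV), one per electrode, with the
#'   sampling rate as attribute `"fs"`.
#' @export
synthesize_extracellular <- function(raster, culture,
                                     electrodes = NULL,
                                     duration,
                                     stim_times = NULL,
                                     band = c(100, 3500),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- culture$config
  fs <- cfg$fs
  electrodes <- electrodes %||% c(cfg$efferent_electrode, cfg$afferent_electrode)
  n_samp <- round(duration * fs)
  tmpl <- spike_template(fs)
  art <- artifact_template(fs) * cfg$artifact_amp
  layout <- culture$layout
  nb_aff <- mea_neighbors(cfg$afferent_electrode, layout)

  out <- list()
  for (e in electrodes) {
    tr <- rnorm(n_samp, 0, cfg$noise_rms)
    el <- layout[layout$electrode == e, ]
    dd <- sqrt((culture$neurons$x_um - el$x_um)^2 +
                 (culture$neurons$y_um - el$y_um)^2)
    amp_here <- culture$neurons$amplitude_uv * exp(-dd / cfg$amp_lambda_um)
    audible <- which(amp_here > 3)
    if (nrow(raster) > 0 && length(audible) > 0) {
      sel <- raster$neuron %in% audible
      if (any(sel)) {
        idx0 <- floor(raster$time_s[sel] * fs) + 1L
        amps <- amp_here[match(raster$neuron[sel], seq_along(amp_here))]
        # spike polarity: negative-first template scaled per neuron
        for (k in seq_along(idx0)) {
          i0 <- idx0[k]
          i1 <- min(i0 + length(tmpl) - 1L, n_samp)
          if (i0 <= n_samp)
            tr[i0:i1] <- tr[i0:i1] + amps[k] * tmpl[seq_len(i1 - i0 + 1L)]
        }
      }
    }
    if (!is.null(stim_times) && length(stim_times) > 0) {
      gain <- if (e == cfg$afferent_electrode) 1
              else if (e %in% nb_aff) cfg$crosstalk_gain
              else 0
      if (gain > 0) {
        idx0 <- floor(stim_times * fs) + 1L
        for (i0 in idx0) {
          i1 <- min(i0 + length(art) - 1L, n_samp)
          if (i0 <= n_samp)
            tr[i0:i1] <- tr[i0:i1] + gain * art[seq_len(i1 - i0 + 1L)]
        }
      }
    }
    if (!is.null(band) && !anyNA(band)) {
      bf <- signal::butter(2, band / (fs / 2), type = "pass")
      tr <- signal::filtfilt(bf, tr)
    }
    if (is.finite(cfg$saturation_uv) && cfg$saturation_uv > 0) {
      tr[tr > cfg$saturation_uv] <- cfg$saturation_uv
      tr[tr < -cfg$saturation_uv] <- -cfg$saturation_uv
    }
    attr(tr, "fs") <- fs
    out[[as.character(e)]] <- tr
  }
  out
}

#' Simulate the culture surrogate (open loop)
#'
#' Runs the network for a given duration with optional externally supplied
#' stimulation (no robot coupling) and synthesizes the extracellular traces.
#'
#' @param config a [culture_config()].
#' @param stim_train a [stim_trigger_train()] of stimulation times, or `NULL`.
#' @param duration duration (s).
#' @param seed integer seed (required).
#' @param electrodes electrodes to synthesize; `NULL` gives the efferent and
#'   afferent sites, `"all"` gives all 60.
#' @param band band-pass corners for trace synthesis.
#' @return list with `raster` (data.frame `neuron`, `time_s`), `traces`
#'   (named list of traces), and `culture`.
#' @export
simulate_culture <- function(config = culture_config(), stim_train = NULL,
                             duration = 10, seed = NULL,
                             electrodes = NULL, band = c(100, 3500)) {
  if (is.null(seed))
    stop("a seed is required (reproducibility contract)", call. = FALSE)
  culture <- build_culture(config, seed)
  stim_ticks <- integer(0)
  if (!is.null(stim_train) && length(stim_train$spike_times) > 0)
    stim_ticks <- as.integer(floor(stim_train$spike_times * 1000))
  res <- .engine_call(culture, n_ticks = round(duration * 1000),
                      efferent_mode = 2L,
                      deliver_stim = length(stim_ticks) > 0,
                      run_encoder = FALSE,
                      external_stim_ticks = stim_ticks,
                      encoding = "SA",
                      decoder = decoder_config(), plant = plant_config(),
                      gains = encoder_gains(), izh = izhikevich_params())
  raster <- data.frame(neuron = res$spike_neuron,
                       time_s = res$spike_time_ms / 1000)
  if (identical(electrodes, "all")) electrodes <- mea_layout()$electrode
  traces <- synthesize_extracellular(raster, culture, electrodes, duration,
                                     stim_times = res$stim_ticks / 1000,
                                     band = band)
  list(raster = raster, traces = traces, culture = culture,
       stim_times = res$stim_ticks / 1000)
}

# Shared bridge into the compiled tick engine.
.engine_call <- function(culture, n_ticks, efferent_mode, deliver_stim,
                         run_encoder, external_stim_ticks = integer(0),
                         warmup_s = 10,
                         encoding = "SA",
                         decoder = decoder_config(), plant = plant_config(),
                         gains = encoder_gains(), izh = izhikevich_params(),
                         es_freq = 0.25) {
  cfg <- culture$config
  nn <- culture$neurons
  v0 <- rep(-65, nrow(nn))
  u0 <- nn$b * v0
  cpp_run_session(
    n_ticks = as.integer(n_ticks),
    warmup_ticks = as.integer(round(warmup_s * 1000)),
    substeps = 2L, dt = 0.5,
    na = nn$a, nb = nn$b, nc = nn$c, nd = nn$d,
    v0 = v0, u0 = u0, noise_sd = nn$noise_sd, is_exc = nn$exc,
    pre_ptr = culture$pre_ptr, post_idx = culture$post_idx,
    w = culture$weights,
    U_dep = cfg$depression_u, tau_rec = cfg$depression_tau,
    tau_syn = cfg$tau_syn,
    slow_inc = cfg$adaptation_inc, tau_slow = cfg$adaptation_tau,
    is_efferent = nn$efferent, stim_coupling = nn$stim_coupling,
    stim_amp = cfg$stim_gain, stim_dur_ticks = 1L,
    stim_dep_u = cfg$stim_dep_u, stim_dep_tau = cfg$stim_dep_tau,
    stim_adapt = cfg$stim_adapt, stim_adapt_rise = cfg$stim_adapt_rise,
    efferent_mode = as.integer(efferent_mode),
    deliver_stim = deliver_stim, run_encoder = run_encoder,
    external_stim_ticks = as.integer(external_stim_ticks),
    bin_ticks = as.integer(decoder$bin_ms), s_thres = as.integer(decoder$s_thres),
    ttl_ticks = as.integer(decoder$ttl_ms),
    theta1 = decoder$theta1, theta2 = decoder$theta2,
    theta_c = plant$theta_c, tau_ms = plant$tau_ms,
    release_tau_ms = plant$release_tau_ms, deadband = plant$deadband_deg,
    stiffness = plant$stiffness, force_noise_sd = plant$sensor_noise_sd,
    smooth_n = as.integer(plant$smooth_samples),
    enc_mode = if (encoding == "SA") 0L else 1L,
    enc_alpha = gains$alpha, enc_beta = gains$beta,
    k_sa = gains$k_sa, k_ra = gains$k_ra,
    e_a = izh$a, e_b = izh$b, e_c = izh$c, e_d = izh$d,
    e_X = izh$X, e_Y = izh$Y, e_Z = izh$Z,
    es_period_ticks = as.integer(round(1000 / es_freq)))
}

#' Check for stimulation crosstalk at neighboring electrodes
#'
#' For every stimulation time, compares the peak deflection at the
#' stimulation site with the peak at each of its 8 grid neighbors inside a
#' short coincidence window. Electrical crosstalk propagates through the
#' medium at every pulse, so an electrode violates the exclusion criterion
#' only if its coincident deflection exceeds the limit (half the
#' stimulation-site artifact -- full width, half amplitude drop -- or the
#' spike detection threshold, whichever is lower) in a consistent fraction
#' of stimulations; occasional coincident spontaneous spikes do not.
#'
#' @param traces named list of traces (names are electrode ids) including
#'   the stimulation site and its neighbors.
#' @param stim_times stimulation times (s).
#' @param v_thresh spike detection threshold (uV).
#' @param stim_electrode stimulation electrode id.
#' @param fs sampling rate (Hz).
#' @param layout layout from [mea_layout()].
#' @param window_ms coincidence window around each stimulation (ms).
#' @param consistency fraction of stimulations above the limit that marks an
#'   electrode as crosstalk-contaminated (default 0.5).
#' @return list with `pass` (logical), `violations` (data.frame `electrode`,
#'   `frac_exceeding`, `max_amplitude_uv`, `limit_uv`), `exceedances`
#'   (per-stimulation detail) and `checked` (electrode ids).
#' @export
verify_no_crosstalk <- function(traces, stim_times, v_thresh,
                                stim_electrode, fs,
                                layout = mea_layout(), window_ms = 2,
                                consistency = 0.5) {
  nb <- mea_neighbors(stim_electrode, layout)
  nb <- nb[as.character(nb) %in% names(traces)]
  empty <- data.frame(electrode = integer(0), frac_exceeding = numeric(0),
                      max_amplitude_uv = numeric(0), limit_uv = numeric(0))
  exc <- data.frame(electrode = integer(0), time_s = numeric(0),
                    amplitude_uv = numeric(0), limit_uv = numeric(0))
  if (length(stim_times) == 0) {
    return(list(pass = TRUE, violations = empty, exceedances = exc,
                checked = nb))
  }
  stim_tr <- traces[[as.character(stim_electrode)]]
  w <- max(1L, round(window_ms / 1000 * fs))
  n <- length(stim_tr)
  for (t in stim_times) {
    i0 <- max(1L, floor(t * fs) + 1L)
    i1 <- min(n, i0 + w)
    ref <- max(abs(stim_tr[i0:i1]))
    limit <- min(ref / 2, v_thresh)
    for (e in nb) {
      amp <- max(abs(traces[[as.character(e)]][i0:i1]))
      if (amp >= limit) {
        exc <- rbind(exc, data.frame(electrode = e, time_s = t,
                                     amplitude_uv = amp, limit_uv = limit))
      }
    }
  }
  viol <- empty
  for (e in nb) {
    k <- sum(exc$electrode == e)
    frac <- k / length(stim_times)
    if (frac >= consistency) {
      viol <- rbind(viol, data.frame(
        electrode = e, frac_exceeding = frac,
        max_amplitude_uv = max(exc$amplitude_uv[exc$electrode == e]),
        limit_uv = min(exc$limit_uv[exc$electrode == e])))
    }
  }
  list(pass = nrow(viol) == 0, violations = viol, exceedances = exc,
       checked = nb)
}
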