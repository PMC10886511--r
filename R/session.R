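# Embodiment sessions: wire the culture surrogate, efferent decoder, robot
# plant and afferent encoder together under the CL/AD/ES switch semantics.

#' Embodiment session configuration
#'
#' The three embodiment configurations fix the two loop switches: CL (closed
#' loop) decodes the efferent electrode into finger taps and stimulates the
#' encoded tactile feedback back; AD (afferent deprived) decodes taps but
#' never delivers stimulation; ES (efferent substitution) drives the finger
#' with a fixed 0.25 Hz square wave while delivering stimulation. Explicit
#' switch values inconsistent with the mode are a configuration error.
#'
#' @param mode `"CL"`, `"AD"` or `"ES"`.
#' @param encoding mechanoreceptor encoding, `"SA"` or `"RA"`.
#' @param duration session duration (s), default 300 (5 min).
#' @param div_label replicate label, e.g. `"DIV21"`.
#' @param seed integer seed (required).
#' @param culture_seed seed for the culture itself; defaults to `seed`.
#'   Sessions recorded on the same day share one dish, so protocols give
#'   all sessions of a DIV the same culture seed while the session seed
#'   varies the ongoing activity.
#' @param efferent_switch `"BNN"` or `"waveform"`; derived from `mode` when
#'   `NULL`.
#' @param afferent_switch `"stimulate"` or `"deprive"`; derived from `mode`
#'   when `NULL`.
#' @param culture a [culture_config()].
#' @param decoder a [decoder_config()].
#' @param plant a [plant_config()].
#' @param gains an [encoder_gains()].
#' @param izh an [izhikevich_params()] for the encoder neuron.
#' @param es_freq ES drive frequency (Hz), default 0.25.
#' @return object of class `embodiment_config`.
#' @export
embodiment_config <- function(mode = c("CL", "AD", "ES"),
                              encoding = c("SA", "RA"),
                              duration = 300, div_label = "DIV21",
                              seed = NULL, culture_seed = NULL,
                              efferent_switch = NULL, afferent_switch = NULL,
                              culture = culture_config(),
                              decoder = decoder_config(),
                              plant = plant_config(),
                              gains = encoder_gains(),
                              izh = izhikevich_params(),
                              es_freq = 0.25) {
  mode <- match.arg(mode)
  encoding <- match.arg(encoding)
  if (is.null(seed)) stop("a seed is required (reproducibility contract)",
                          call. = FALSE)
  want_eff <- if (mode == "ES") "waveform" else "BNN"
  want_aff <- if (mode == "AD") "deprive" else "stimulate"
  efferent_switch <- efferent_switch %||% want_eff
  afferent_switch <- afferent_switch %||% want_aff
  if (efferent_switch != want_eff || afferent_switch != want_aff)
    stop("inconsistent switch combination for mode ", mode,
         ": requires efferent ", want_eff, " / afferent ", want_aff,
         call. = FALSE)
  stopifnot(duration > 0, decoder$theta1 < plant$theta_c,
            plant$theta_c < decoder$theta2)
  structure(list(mode = mode, encoding = encoding, duration = duration,
                 div_label = div_label, seed = as.integer(seed),
                 culture_seed = as.integer(culture_seed %||% seed),
                 efferent_switch = efferent_switch,
                 afferent_switch = afferent_switch,
                 culture = culture, decoder = decoder, plant = plant,
                 gains = gains, izh = izh, es_freq = es_freq),
            class = "embodiment_config")
}

# cheap structural checksum of a configuration (no external digest needed)
.config_checksum <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "seed")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251 + 1)) %% 4294967291)
}

#' Run one embodiment session
#'
#' Executes the full closed loop at a 1 kHz control tick (0.5 ms network
#' substeps): culture surrogate, spike-bin decoder, first-order plant with
#' elastic fingertip contact, and SA/RA Izhikevich encoder with a one-tick
#' loop latency. Extracellular traces for the efferent and afferent sites
#' are synthesized at the configured rate afterwards.
#'
#' @param embodiment an [embodiment_config()].
#' @param synthesize synthesize extracellular traces (default `TRUE`).
#' @param band band-pass corners (Hz) for trace synthesis.
#' @return object of class `session_record` with elements `theta`, `forces`
#'   (a `force_signal`), `ttl` (data.frame of pulse onsets/offsets),
#'   `tap_times` (contact onsets, s), `stim_train` (delivered stimulation;
#'   empty in AD), `encoder_train` (encoder output regardless of delivery),
#'   `raster`, `traces` (`$efferent`, `$afferent`), `fs`, `control_rate`,
#'   `duration` and `meta`.
#' @export
run_session <- function(embodiment, synthesize = TRUE, band = c(100, 3500)) {
  stopifnot(inherits(embodiment, "embodiment_config"))
  culture <- build_culture(embodiment$culture,
                           seed = embodiment$culture_seed %||% embodiment$seed)
  set.seed(embodiment$seed)
  n_ticks <- round(embodiment$duration * 1000)
  eff_mode <- switch(embodiment$mode, CL = 0L, AD = 0L, ES = 1L)
  res <- .engine_call(
    culture, n_ticks = n_ticks, efferent_mode = eff_mode,
    deliver_stim = embodiment$afferent_switch == "stimulate",
    run_encoder = TRUE,
    encoding = embodiment$encoding,
    decoder = embodiment$decoder, plant = embodiment$plant,
    gains = embodiment$gains, izh = embodiment$izh,
    es_freq = embodiment$es_freq)

  rate <- 1000
  theta <- res$theta
  contact <- theta >= embodiment$plant$theta_c
  tap_times <- (which(diff(c(FALSE, contact)) == 1) - 1) / rate
  forces <- structure(list(f_dc = res$f_dc, f_ac = res$f_ac,
                           timestamps = (seq_len(n_ticks) - 1) / rate,
                           rate = rate),
                      class = "force_signal")
  ttl <- data.frame(onset_s = res$ttl_onset_ticks / rate,
                    offset_s = (res$ttl_onset_ticks +
                                  embodiment$decoder$ttl_ms) / rate)
  raster <- data.frame(neuron = res$spike_neuron,
                       time_s = res$spike_time_ms / 1000)
  stim_times <- res$stim_ticks / rate
  enc_times <- res$encoder_ticks / rate
  mk_train <- function(t) {
    t <- t[!duplicated(t)]
    stim_trigger_train(t, encoding = embodiment$encoding)
  }
  traces <- NULL
  if (synthesize) {
    traces0 <- synthesize_extracellular(
      raster, culture, duration = embodiment$duration,
      stim_times = stim_times, band = band)
    traces <- list(
      efferent = traces0[[as.character(embodiment$culture$efferent_electrode)]],
      afferent = traces0[[as.character(embodiment$culture$afferent_electrode)]])
  }
  structure(list(
    theta = theta, forces = forces, ttl = ttl, tap_times = tap_times,
    stim_train = mk_train(stim_times), encoder_train = mk_train(enc_times),
    raster = raster, traces = traces,
    efferent_counts = res$efferent_counts,
    fs = embodiment$culture$fs, control_rate = rate,
    duration = embodiment$duration,
    meta = list(mode = embodiment$mode, encoding = embodiment$encoding,
                div = embodiment$div_label, seed = embodiment$seed,
                efferent_electrode = embodiment$culture$efferent_electrode,
                afferent_electrode = embodiment$culture$afferent_electrode,
                config_checksum = .config_checksum(unclass(embodiment)))
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %s / %s / %s | %.0f s | %d taps, %d TTL pulses, %d stim, %d spikes\n",
    x$meta$mode, x$meta$encoding, x$meta$div, x$duration,
    length(x$tap_times), nrow(x$ttl), length(x$stim_train$spike_times),
    nrow(x$raster)))
  invisible(x)
}

#' Run the multi-day recording protocol
#'
#' Runs every combination of replicate day, embodiment mode and encoding
#' (default 3 DIV x {CL, AD, ES} x {SA, RA} = 18 sessions), each with its own
#' derived seed.
#'
#' @param n_div number of replicate days.
#' @param modes embodiment modes to run.
#' @param encodings encodings to run.
#' @param base_seed base seed; per-session seeds are derived with
#'   [derive_seed()].
#' @param duration session duration (s).
#' @param dry_run if `TRUE`, return the session plan (with seeds) without
#'   simulating.
#' @param div_start first DIV label number (default 21).
#' @param ... further arguments to [embodiment_config()].
#' @return if `dry_run`, a data.frame plan; otherwise a list of
#'   `session_record`s named `"{div}_{mode}_{encoding}"`.
#' @export
run_protocol <- function(n_div = 3, modes = c("CL", "AD", "ES"),
                         encodings = c("SA", "RA"), base_seed = 1,
                         duration = 300, dry_run = FALSE, div_start = 21,
                         ...) {
  stopifnot(n_div >= 1)
  plan <- expand.grid(encoding = encodings, mode = modes,
                      div = paste0("DIV", div_start + seq_len(n_div) - 1),
                      stringsAsFactors = FALSE)[, 3:1]
  plan$seed <- vapply(seq_len(nrow(plan)),
                      function(i) derive_seed(base_seed, i), integer(1))
  # all sessions of one day run on the same dish
  plan$culture_seed <- derive_seed(base_seed, 9000 + match(plan$div,
                                                           unique(plan$div)))
  plan$id <- sprintf("%s_%s_%s", plan$div, plan$mode, plan$encoding)
  if (dry_run) return(plan)
  out <- vector("list", nrow(plan))
  names(out) <- plan$id
  for (i in seq_len(nrow(plan))) {
    cfg <- embodiment_config(mode = plan$mode[i], encoding = plan$encoding[i],
                             duration = duration, div_label = plan$div[i],
                             seed = plan$seed[i],
                             culture_seed = plan$culture_seed[i], ...)
    out[[i]] <- run_session(cfg)
  }
  out
}

#' Record a stimulus-free baseline
#'
#' Runs the culture surrogate with no stimulation and no robot coupling to
#' obtain spontaneous activity, as done at the start of each recording day.
#'
#' @param duration duration (s), default 300.
#' @param seed integer seed (required).
#' @param culture a [culture_config()].
#' @param synthesize synthesize the extracellular traces.
#' @param band band-pass corners (Hz).
#' @return a `session_record` with empty `ttl`, `tap_times` and `stim_train`.
#' @export
record_baseline <- function(duration = 300, seed = NULL,
                            culture = culture_config(),
                            synthesize = TRUE, band = c(100, 3500)) {
  if (is.null(seed)) stop("a seed is required (reproducibility contract)",
                          call. = FALSE)
  set.seed(seed)
  cl <- build_culture(culture, seed = seed)
  res <- .engine_call(cl, n_ticks = round(duration * 1000),
                      efferent_mode = 2L, deliver_stim = FALSE,
                      run_encoder = FALSE)
  raster <- data.frame(neuron = res$spike_neuron,
                       time_s = res$spike_time_ms / 1000)
  traces <- NULL
  if (synthesize) {
    traces0 <- synthesize_extracellular(raster, cl, duration = duration,
                                        band = band)
    traces <- list(efferent = traces0[[as.character(culture$efferent_electrode)]],
                   afferent = traces0[[as.character(culture$afferent_electrode)]])
  }
  structure(list(
    theta = res$theta, forces = NULL,
    ttl = data.frame(onset_s = numeric(0), offset_s = numeric(0)),
    tap_times = numeric(0),
    stim_train = stim_trigger_train(numeric(0)),
    encoder_train = stim_trigger_train(numeric(0)),
    raster = raster, traces = traces,
    efferent_counts = res$efferent_counts,
    fs = culture$fs, control_rate = 1000, duration = duration,
    meta = list(mode = "baseline", encoding = NA, div = NA, seed = seed,
                efferent_electrode = culture$efferent_electrode,
                afferent_electrode = culture$afferent_electrode)
  ), class = "session_record")
}

#' Write a session record as a plain-text bundle
#'
#' Persists a session as a directory of CSV files plus a JSON metadata file
#' (streams `robot.csv`, `events.csv`, `raster.csv`, `stim.csv`, optionally
#' the raw traces).
#'
#' @param session a `session_record`.
#' @param dir target directory (created if needed).
#' @param write_traces also write the (large) extracellular traces as CSV.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, write_traces = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(session$forces)) {
    robot <- data.frame(time_s = session$forces$timestamps,
                        theta_deg = session$theta,
                        f_dc = session$forces$f_dc,
                        f_ac = session$forces$f_ac)
    write.csv(robot, file.path(dir, "robot.csv"), row.names = FALSE)
  }
  write.csv(session$ttl, file.path(dir, "ttl.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = session$tap_times),
            file.path(dir, "taps.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = session$stim_train$spike_times,
                       level_v = session$stim_train$trigger_level,
                       encoding = session$stim_train$encoding),
            file.path(dir, "stim.csv"), row.names = FALSE)
  write.csv(session$raster, file.path(dir, "raster.csv"), row.names = FALSE)
  if (write_traces && !is.null(session$traces)) {
    write.csv(data.frame(efferent_uv = session$traces$efferent,
                         afferent_uv = session$traces$afferent),
              file.path(dir, "traces.csv"), row.names = FALSE)
  }
  meta <- session$meta
  meta$fs <- session$fs
  meta$duration <- session$duration
  meta$control_rate <- session$control_rate
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir bundle directory.
#' @return a `session_record` (without traces unless they were written).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  robot_path <- file.path(dir, "robot.csv")
  theta <- NULL; forces <- NULL
  if (file.exists(robot_path)) {
    robot <- read.csv(robot_path)
    theta <- robot$theta_deg
    forces <- structure(list(f_dc = robot$f_dc, f_ac = robot$f_ac,
                             timestamps = robot$time_s,
                             rate = meta$control_rate),
                        class = "force_signal")
  }
  stim <- read.csv(file.path(dir, "stim.csv"))
  traces <- NULL
  if (file.exists(file.path(dir, "traces.csv"))) {
    tr <- read.csv(file.path(dir, "traces.csv"))
    traces <- list(efferent = tr$efferent_uv, afferent = tr$afferent_uv)
  }
  enc <- if (nrow(stim) > 0) stim$encoding[1] else "SA"
  structure(list(
    theta = theta, forces = forces,
    ttl = read.csv(file.path(dir, "ttl.csv")),
    tap_times = read.csv(file.path(dir, "taps.csv"))$time_s,
    stim_train = stim_trigger_train(stim$time_s, encoding = enc),
    encoder_train = NULL,
    raster = read.csv(file.path(dir, "raster.csv")),
    traces = traces,
    fs = meta$fs, control_rate = meta$control_rate,
    duration = meta$duration,
    meta = meta[c("mode", "encoding", "div", "seed",
                  "efferent_electrode", "afferent_electrode")]
  ), class = "session_record")
}
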