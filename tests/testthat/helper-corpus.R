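# Shared simulated-study corpus for the acceptance-level tests.
#
# Analysis-scale conditions used throughout the suite: 10 kHz extracellular
# traces (the 100-4000 Hz band sits below Nyquist), 5-minute sessions as in
# the recording protocol, 16 CWT voices for the event detector, and event
# windows analyzed at 500 Hz (the 50 ms-smoothed envelopes carry no content
# above a few tens of Hz).

corpus_culture <- function() culture_config(fs = 10000)
corpus_cwt <- function() cwt_config(n_freqs = 16)
corpus_coh <- function() coherence_config(micro_rate = 500, voices = 8)

.corpus_env <- new.env(parent = emptyenv())

# One simulated study day: CL and AD sessions for both encodings on one DIV.
# Returns per-session events, ITIs and TFIs; memoized per (base_seed, div).
corpus_day <- function(div_index, base_seed = 1, duration = 300) {
  key <- sprintf("day_%d_%d_%d", base_seed, div_index, duration)
  if (!is.null(.corpus_env[[key]])) return(.corpus_env[[key]])
  cwtc <- corpus_cwt()
  coh <- corpus_coh()
  out <- list()
  for (mode in c("CL", "AD")) {
    for (enc in c("SA", "RA")) {
      idx <- div_index * 100 + match(mode, c("CL", "AD")) * 10 +
        match(enc, c("SA", "RA"))
      cfg <- embodiment_config(
        mode = mode, encoding = enc, duration = duration,
        div_label = paste0("DIV", 20 + div_index),
        seed = derive_seed(base_seed, idx),
        culture_seed = derive_seed(base_seed, 9000 + div_index),
        culture = corpus_culture())
      s <- run_session(cfg)
      masp <- session_masp(s, cwtc)
      ev <- detect_events(masp$efferent, cwtc)
      tfis <- suppressMessages(session_tfis(s, ev, coh, cwtc, masp = masp))
      # keep the day light in memory: envelopes decimated to 1 kHz, no traces
      masp1k <- list(
        efferent = masp_series(pmax(0, decimate_series(
          masp$efferent$values, masp$efferent$fs, 1000)), 1000),
        afferent = masp_series(pmax(0, decimate_series(
          masp$afferent$values, masp$afferent$fs, 1000)), 1000))
      s$traces <- NULL
      s$raster <- NULL
      out[[paste(mode, enc, sep = "_")]] <- list(
        session = s, masp = masp1k, events = ev,
        itis = compute_iti(ev$timestamp_s), tfis = tfis)
      rm(masp)
      gc(FALSE)
    }
  }
  .corpus_env[[key]] <- out
  out
}
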