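# Efferent decoding: extracellular trace -> spikes -> binned TTL taps -> joint
# angle commands.

#' Efferent decoder configuration
#'
#' Thresholding, binning and tap-command parameters for the efferent decoding
#' chain. Spikes are samples where the trace meets or exceeds `v_thresh`
#' (collapsed within a refractory window); spikes are summed over consecutive
#' non-overlapping `bin_ms` windows; a bin reaching `s_thres` spikes emits one
#' TTL pulse of `ttl_ms`, during which the desired joint angle is `theta2`
#' (contact) instead of `theta1` (open hand).
#'
#' @param v_thresh spike detection threshold (uV). `NULL` defers to
#'   5x the robust noise RMS of the trace at detection time.
#' @param bin_ms bin size (ms), default 50.
#' @param s_thres spike-count threshold per bin, default 3.
#' @param ttl_ms TTL pulse width (ms), default 100.
#' @param theta1 open-hand joint angle (deg).
#' @param theta2 contact joint angle (deg); must exceed `theta1`.
#' @param refractory_ms window within which consecutive suprathreshold
#'   samples count as one spike (ms).
#' @param sliding if `TRUE`, bins slide sample by sample instead of tumbling.
#' @return object of class `decoder_config`.
#' @export
decoder_config <- function(v_thresh = NULL, bin_ms = 50, s_thres = 3,
                           ttl_ms = 100, theta1 = 0, theta2 = 45,
                           refractory_ms = 1, sliding = FALSE) {
  stopifnot(bin_ms > 0, s_thres >= 1, theta2 > theta1, ttl_ms > 0)
  structure(list(v_thresh = v_thresh, bin_ms = bin_ms, s_thres = s_thres,
                 ttl_ms = ttl_ms, theta1 = theta1, theta2 = theta2,
                 refractory_ms = refractory_ms, sliding = sliding),
            class = "decoder_config")
}

#' Detect spikes by amplitude thresholding
#'
#' Marks samples where the trace meets or exceeds the threshold (a sample at
#' exactly `v_thresh` counts). Runs of suprathreshold samples within one
#' refractory window are collapsed onto their first sample so a single action
#' potential is counted once.
#'
#' @param trace extracellular voltage trace (uV).
#' @param fs sampling rate (Hz).
#' @param v_thresh detection threshold (uV); `NULL` uses 5x the robust noise
#'   RMS of `trace`.
#' @param refractory_ms refractory window (ms).
#' @return integer 0/1 vector, same length as `trace`.
#' @export
detect_spikes <- function(trace, fs, v_thresh = NULL, refractory_ms = 1) {
  stopifnot_finite(trace, "trace")
  noise <- estimate_noise_rms(trace)
  v_thresh <- v_thresh %||% (5 * noise)
  if (v_thresh <= noise)
    warning("spike threshold (", signif(v_thresh, 3),
            " uV) does not exceed the noise RMS (", signif(noise, 3),
            " uV); crosstalk may be counted as spikes", call. = FALSE)
  above <- which(trace >= v_thresh)
  s <- integer(length(trace))
  if (length(above)) {
    refr <- max(1L, round(refractory_ms / 1000 * fs))
    last <- -Inf
    for (i in above) {
      if (i - last >= refr) {
        s[i] <- 1L
        last <- i
      }
    }
  }
  s
}

#' Bin spikes and emit TTL tap pulses
#'
#' Sums the binary spike series over consecutive non-overlapping bins (or a
#' sliding window if configured). A bin whose count reaches `s_thres` emits a
#' TTL pulse of `ttl_ms` starting at the bin end; while a pulse is active no
#' new pulse can start and bins ending inside it cannot emit.
#'
#' @param s binary spike series from [detect_spikes()].
#' @param fs sampling rate of `s` (Hz).
#' @param config a [decoder_config()].
#' @return data.frame with `onset_s` and `offset_s` of each TTL pulse.
#' @export
bin_and_trigger <- function(s, fs, config = decoder_config()) {
  n <- length(s)
  bin <- max(1L, round(config$bin_ms / 1000 * fs))
  ttl <- max(1L, round(config$ttl_ms / 1000 * fs))
  onsets <- integer(0)
  active_until <- -Inf
  if (!config$sliding) {
    n_bins <- n %/% bin
    if (n_bins > 0) {
      counts <- colSums(matrix(s[seq_len(n_bins * bin)], nrow = bin))
      ends <- seq_len(n_bins) * bin
      for (k in seq_len(n_bins)) {
        if (counts[k] >= config$s_thres && ends[k] > active_until) {
          onsets <- c(onsets, ends[k])
          active_until <- ends[k] + ttl - 1L
        }
      }
    }
  } else {
    cs <- cumsum(s)
    for (e in seq(bin, n)) {
      cnt <- cs[e] - if (e - bin >= 1) cs[e - bin] else 0
      if (cnt >= config$s_thres && e > active_until) {
        onsets <- c(onsets, e)
        active_until <- e + ttl - 1L
      }
    }
  }
  data.frame(onset_s = onsets / fs, offset_s = (onsets + ttl) / fs)
}

#' Desired joint-angle timeline from TTL pulses
#'
#' The desired angle is `theta2` while a TTL pulse is active and `theta1`
#' otherwise, sampled on a regular grid.
#'
#' @param pulses data.frame from [bin_and_trigger()].
#' @param duration timeline duration (s).
#' @param rate sampling rate of the timeline (Hz).
#' @param config a [decoder_config()].
#' @return numeric vector of desired angles (deg), length `duration * rate`.
#' @export
command_joint_angle <- function(pulses, duration, rate = 1000,
                                config = decoder_config()) {
  n <- round(duration * rate)
  theta <- rep(config$theta1, n)
  for (k in seq_len(nrow(pulses))) {
    i0 <- floor(pulses$onset_s[k] * rate) + 1L
    i1 <- min(ceiling(pulses$offset_s[k] * rate), n)
    if (i0 <= n) theta[i0:i1] <- config$theta2
  }
  theta
}
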