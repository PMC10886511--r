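# Neurotactile event detection: complex-Morlet CWT power, scaled/clipped and
# frequency-averaged into the MASP envelope, then peak detection and ITIs.

#' CWT event-detector configuration
#'
#' Parameters of the neurotactile event detector: a complex Morlet CWT over a
#' 100-4000 Hz band, amplitude-squared power scaled to `[0, 1]`, clipped to
#' `clip_range` to suppress artifacts, averaged across frequency, smoothed
#' with a 50 ms moving mean and renormalized; events are peaks above
#' `peak_threshold` separated by at least `min_peak_distance_s`.
#'
#' @param freq_range analysis band (Hz), default `c(100, 4000)`.
#' @param n_freqs number of log-spaced center frequencies (voices).
#' @param clip_range two ascending values in `(0, 1]`; the informative band
#'   of scaled power (default `c(0.05, 0.4)`).
#' @param clip_mode `"band"` (default) zeroes values below the floor
#'   (sub-noise power) and saturates values above the ceiling (coincident
#'   spikes, artifacts), so the envelope is monotone in spike density;
#'   `"zero"` zeroes values outside the range on both sides; `"saturate"`
#'   clamps both sides to the range.
#' @param smooth_ms moving-mean window (ms), default 50.
#' @param peak_threshold normalized peak threshold, default 0.5.
#' @param min_peak_distance_s minimum peak separation (s), default 0.5.
#' @param omega0 Morlet center frequency (rad), default 6.
#' @return object of class `cwt_config`.
#' @export
cwt_config <- function(freq_range = c(100, 4000), n_freqs = 64,
                       clip_range = c(0.05, 0.4),
                       clip_mode = c("band", "zero", "saturate"),
                       smooth_ms = 50, peak_threshold = 0.5,
                       min_peak_distance_s = 0.5, omega0 = 6) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(length(freq_range) == 2, freq_range[1] > 0,
            freq_range[2] > freq_range[1], n_freqs >= 2,
            clip_range[1] > 0, clip_range[2] > clip_range[1],
            clip_range[2] <= 1)
  structure(list(freq_range = freq_range, n_freqs = n_freqs,
                 clip_range = clip_range, clip_mode = clip_mode,
                 smooth_ms = smooth_ms, peak_threshold = peak_threshold,
                 min_peak_distance_s = min_peak_distance_s, omega0 = omega0),
            class = "cwt_config")
}

# Fourier factor of the Morlet wavelet: period = factor * scale.
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Complex Morlet continuous wavelet transform
#'
#' FFT-based analytic Morlet CWT at the requested center frequencies. Long
#' inputs are processed in overlapping chunks (overlap-save) so memory and
#' FFT cost stay bounded; results are identical to the single-FFT transform
#' away from machine precision.
#'
#' @param x real signal.
#' @param fs sampling rate (Hz).
#' @param freqs center frequencies (Hz), all below Nyquist.
#' @param omega0 Morlet center frequency (rad).
#' @param chunk chunk length in samples for long inputs.
#' @return complex matrix, `length(freqs)` rows x `length(x)` columns.
#' @export
morlet_cwt <- function(x, fs, freqs, omega0 = 6, chunk = 2^17) {
  stopifnot(all(freqs > 0), all(freqs < fs / 2))
  n <- length(x)
  ff <- morlet_fourier_factor(omega0)
  scales <- 1 / (ff * freqs) * fs            # scales in samples
  support <- ceiling(6 * max(scales)) + 1L
  if (n < support)
    stop("trace shorter than the longest wavelet support (", support,
         " samples)", call. = FALSE)
  if (n <= chunk + 2L * support) {
    return(.cwt_block(x, scales, omega0))
  }
  out <- matrix(0i, nrow = length(freqs), ncol = n)
  step <- chunk - 2L * support
  starts <- seq(1L, n, by = step)
  for (s0 in starts) {
    lo <- max(1L, s0 - support)
    hi <- min(n, s0 + step - 1L + support)
    blk <- .cwt_block(x[lo:hi], scales, omega0)
    keep_lo <- s0 - lo + 1L
    keep_hi <- min(s0 + step - 1L, n) - lo + 1L
    out[, s0:(s0 + keep_hi - keep_lo)] <- blk[, keep_lo:keep_hi, drop = FALSE]
  }
  out
}

# Single-block analytic Morlet CWT via FFT.
.cwt_block <- function(x, scales, omega0) {
  n <- length(x)
  nfft <- next_pow2(n)
  xf <- stats::fft(c(x, numeric(nfft - n)))
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  pos <- omega > 0
  out <- matrix(0i, nrow = length(scales), ncol = n)
  # cosine taper to zero at Nyquist: an abruptly clipped response would ring
  # with slowly decaying time tails and defeat finite-support chunking
  taper <- rep(1, nfft)
  hi <- pos & omega > 0.85 * pi
  taper[hi] <- 0.5 * (1 + cos((omega[hi] - 0.85 * pi) / (0.15 * pi) * pi))
  for (j in seq_along(scales)) {
    h <- numeric(nfft)
    h[pos] <- exp(-0.5 * (scales[j] * omega[pos] - omega0)^2)
    h <- h * taper * sqrt(scales[j])          # relative energy normalization
    w <- stats::fft(xf * h, inverse = TRUE) / nfft
    out[j, ] <- w[seq_len(n)]
  }
  out
}

#' Amplitude-squared power of a trace
#'
#' Squared magnitude of the complex Morlet CWT at log-spaced center
#' frequencies spanning the configured band.
#'
#' @param trace voltage trace (uV).
#' @param fs sampling rate (Hz).
#' @param config a [cwt_config()].
#' @return nonnegative matrix, `n_freqs` rows x `length(trace)` columns, with
#'   the center frequencies attached as attribute `"freqs"`.
#' @export
compute_asp <- function(trace, fs, config = cwt_config()) {
  if (config$freq_range[2] >= fs / 2)
    stop("frequency band exceeds the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  freqs <- exp(seq(log(config$freq_range[1]), log(config$freq_range[2]),
                   length.out = config$n_freqs))
  n <- length(trace)
  ff <- morlet_fourier_factor(config$omega0)
  scales <- 1 / (ff * freqs) * fs
  support <- ceiling(6 * max(scales)) + 1L
  chunk <- 2^17
  if (n <= chunk + 2L * support) {
    asp <- Mod(morlet_cwt(trace, fs, freqs, omega0 = config$omega0))^2
  } else {
    # long traces: fill the real power matrix chunk by chunk so the full
    # complex transform is never materialized
    asp <- matrix(0, nrow = length(freqs), ncol = n)
    step <- chunk - 2L * support
    for (s0 in seq(1L, n, by = step)) {
      lo <- max(1L, s0 - support)
      hi <- min(n, s0 + step - 1L + support)
      blk <- .cwt_block(trace[lo:hi], scales, config$omega0)
      keep_lo <- s0 - lo + 1L
      keep_hi <- min(s0 + step - 1L, n) - lo + 1L
      asp[, s0:(s0 + keep_hi - keep_lo)] <-
        Mod(blk[, keep_lo:keep_hi, drop = FALSE])^2
    }
  }
  attr(asp, "freqs") <- freqs
  asp
}

#' Scale, clip and average power into the MASP envelope
#'
#' Divides the power matrix by its global maximum (scaled range 0-1),
#' clips it to the configured range (zeroing or saturating values outside it,
#' per `clip_mode`), averages across the frequency axis at each time point,
#' smooths with the configured moving mean, and renormalizes to a maximum
#' of 1. An all-zero input maps to an all-zero envelope.
#'
#' @param asp nonnegative power matrix from [compute_asp()].
#' @param fs sampling rate (Hz) of the underlying trace.
#' @param config a [cwt_config()].
#' @return object of class `masp_series`: list with `values` (in `[0, 1]`),
#'   `fs` and `electrode`.
#' @param electrode optional source electrode id carried in the result.
#' @export
scale_clip_masp <- function(asp, fs, config = cwt_config(), electrode = NA) {
  if (any(asp < 0)) stop("power matrix must be nonnegative", call. = FALSE)
  m <- max(asp)
  if (m == 0) {
    return(masp_series(numeric(ncol(asp)) , fs = fs, electrode = electrode))
  }
  lo <- config$clip_range[1] * m
  hi <- config$clip_range[2] * m
  n <- ncol(asp)
  masp <- numeric(n)
  # block-wise over columns to avoid full-matrix copies on long traces
  blk <- 262144L
  for (s0 in seq(1L, n, by = blk)) {
    s1 <- min(n, s0 + blk - 1L)
    b <- asp[, s0:s1, drop = FALSE]
    if (config$clip_mode == "saturate") {
      b[b < lo] <- lo
      b[b > hi] <- hi
    } else if (config$clip_mode == "band") {
      b[b < lo] <- 0
      b[b > hi] <- hi
    } else {
      b[b < lo | b > hi] <- 0
    }
    masp[s0:s1] <- colMeans(b)
  }
  masp <- masp / m
  masp <- moving_average(masp, round(config$smooth_ms / 1000 * fs))
  mm <- max(masp)
  if (mm > 0) masp <- masp / mm
  masp_series(masp, fs = fs, electrode = electrode)
}

#' MASP envelope container
#'
#' @param values nonnegative envelope values (max 1 for non-degenerate input).
#' @param fs sampling rate (Hz).
#' @param electrode source electrode id.
#' @return object of class `masp_series`.
#' @export
masp_series <- function(values, fs, electrode = NA) {
  stopifnot(all(values >= 0), all(is.finite(values)))
  structure(list(values = values, fs = fs, electrode = electrode),
            class = "masp_series")
}

#' Full MASP pipeline for one trace
#'
#' Convenience chain: [compute_asp()] then [scale_clip_masp()].
#'
#' @inheritParams compute_asp
#' @param electrode optional electrode id carried in the result.
#' @return a [masp_series()].
#' @export
compute_masp <- function(trace, fs, config = cwt_config(), electrode = NA) {
  scale_clip_masp(compute_asp(trace, fs, config), fs, config,
                  electrode = electrode)
}

#' Detect neurotactile events in a MASP envelope
#'
#' Local maxima above the configured threshold with the configured minimum
#' peak separation (larger peaks win inside an exclusion window, as in
#' MATLAB's `findpeaks` with `MinPeakDistance`).
#'
#' @param masp a [masp_series()].
#' @param config a [cwt_config()].
#' @return data.frame with `timestamp_s` (strictly increasing) and `iti_s`
#'   (NA for the first event).
#' @export
detect_events <- function(masp, config = cwt_config()) {
  v <- masp$values
  mind <- max(1L, round(config$min_peak_distance_s * masp$fs))
  # allow flat-topped peaks (smoothed envelopes of sparse power plateau)
  pk <- pracma::findpeaks(v, minpeakheight = config$peak_threshold,
                          minpeakdistance = mind,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) {
    return(data.frame(timestamp_s = numeric(0), iti_s = numeric(0)))
  }
  t_idx <- vapply(pk[, 2], function(i) {
    lo <- i
    hi <- i
    while (hi < length(v) && v[hi + 1L] == v[i]) hi <- hi + 1L
    as.integer(round((lo + hi) / 2))
  }, integer(1))
  t_idx <- sort(t_idx)
  ts <- (t_idx - 1) / masp$fs
  data.frame(timestamp_s = ts, iti_s = c(NA_real_, diff(ts)))
}

#' Inter-tap intervals from event timestamps
#'
#' Successive differences of the event timestamps; fewer than two events
#' yield an empty result.
#'
#' @param event_times event timestamps (s), sorted.
#' @return numeric vector of ITIs (s), length `length(event_times) - 1`.
#' @export
compute_iti <- function(event_times) {
  if (length(event_times) < 2) return(numeric(0))
  diff(sort(event_times))
}

#' Write an event table as CSV
#'
#' @param events data.frame from [detect_events()].
#' @param path output CSV file.
#' @param session_id identifier recorded with every row.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, session_id = NA) {
  out <- data.frame(session_id = session_id,
                    timestamp_s = events$timestamp_s,
                    iti_s = events$iti_s)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
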