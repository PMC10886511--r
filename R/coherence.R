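# Wavelet coherence between efferent and afferent MASP envelopes, at the
# micro scale (1 s windows around each neurotactile event) and the macro
# scale (whole session), rendered as fixed-colormap time-frequency images.

#' Coherence / TFI configuration
#'
#' @param micro_pre seconds of envelope before each event timestamp (0.3).
#' @param micro_post seconds after each event timestamp (0.7).
#' @param micro_rate sampling rate (Hz) at which event windows are analyzed;
#'   the session envelope is anti-aliased and decimated to this rate first.
#' @param macro_rate sampling rate (Hz) for whole-session coherence (2000).
#' @param apply_coi mask the cone of influence before rendering.
#' @param image_size rendered image side (pixels); images are
#'   `image_size x image_size x 3`.
#' @param voices wavelet voices per octave for the coherence estimator.
#' @param omega0 analytic Morlet center frequency (rad).
#' @param colormap name of a `grDevices::hcl.colors` palette; the color
#'   scale is fixed to coherence 0-1.
#' @return object of class `coherence_config`.
#' @export
coherence_config <- function(micro_pre = 0.3, micro_post = 0.7,
                             micro_rate = 20000, macro_rate = 2000,
                             apply_coi = TRUE, image_size = 227,
                             voices = 12, omega0 = 6,
                             colormap = "viridis") {
  stopifnot(micro_pre > 0, micro_post > 0, micro_rate > 0,
            macro_rate > 0, image_size >= 8)
  structure(list(micro_pre = micro_pre, micro_post = micro_post,
                 micro_rate = micro_rate, macro_rate = macro_rate,
                 apply_coi = apply_coi, image_size = image_size,
                 voices = voices, omega0 = omega0, colormap = colormap),
            class = "coherence_config")
}

#' Anti-aliased decimation
#'
#' Low-pass filters at 80% of the target Nyquist frequency (8th-order
#' Butterworth, zero-phase) and subsamples to the target rate.
#'
#' @param x numeric series.
#' @param fs current sampling rate (Hz).
#' @param new_rate target rate (Hz); must divide `fs`.
#' @return numeric series at `new_rate`.
#' @export
decimate_series <- function(x, fs, new_rate) {
  if (fs == new_rate) return(x)
  stopifnot(fs %% new_rate == 0)
  bf <- signal::butter(8, 0.8 * new_rate / fs, type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1, length(y), by = fs / new_rate)]
}

#' Magnitude-squared wavelet coherence
#'
#' Analytic Morlet wavelet coherence between two equally sampled series,
#' with scale-proportional Gaussian smoothing in time and a 0.6-octave boxcar
#' smoothing across scales (required for the magnitude-squared coherence to
#' be informative). Scales are dyadic with `voices` sub-octaves from two
#' samples up to a quarter of the series length (bounded by
#' `min_freq`/`max_freq` when given). The cone of influence (COI) marks, for
#' each time point, the longest period unaffected by edge effects.
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate (Hz).
#' @param config a [coherence_config()].
#' @param min_freq,max_freq optional frequency bounds (Hz) for the scale grid.
#' @return list of class `wavelet_coherence`: `coherence` (matrix in `[0,1]`,
#'   scales x time), `freqs` (Hz), `periods` (s), `times` (s), `coi_period`
#'   (s, per time point) and `coi_mask` (TRUE where inside the COI).
#' @export
wavelet_coherence <- function(x, y, fs, config = coherence_config(),
                              min_freq = NULL, max_freq = NULL) {
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  n <- length(x)
  stopifnot(n >= 16)
  dt <- 1 / fs
  omega0 <- config$omega0
  ff <- morlet_fourier_factor(omega0)
  s0 <- 2 * dt
  smax <- n * dt / 4
  if (!is.null(max_freq)) s0 <- max(s0, 1 / (ff * max_freq))
  if (!is.null(min_freq)) smax <- min(smax, 1 / (ff * min_freq))
  n_oct <- log2(smax / s0)
  scales <- s0 * 2^(seq(0, n_oct, by = 1 / config$voices))
  periods <- ff * scales
  nfft <- next_pow2(2L * n)

  xf <- stats::fft(c(x - mean(x), numeric(nfft - n)))
  yf <- stats::fft(c(y - mean(y), numeric(nfft - n)))
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  pos <- omega > 0
  omega_s <- omega / dt                     # rad / second

  ns <- length(scales)
  Sxx <- matrix(0, ns, n); Syy <- matrix(0, ns, n)
  Sxy <- matrix(0i, ns, n)
  for (j in seq_len(ns)) {
    s <- scales[j]
    h <- numeric(nfft)
    h[pos] <- exp(-0.5 * (s * omega_s[pos] - omega0)^2)
    h <- h * sqrt(s / dt)
    wx <- stats::fft(xf * h, inverse = TRUE)[seq_len(n)] / nfft
    wy <- stats::fft(yf * h, inverse = TRUE)[seq_len(n)] / nfft
    # scale-proportional Gaussian time smoothing, via FFT
    g <- exp(-0.5 * (s * omega_s)^2)
    sm <- function(z) {
      zf <- stats::fft(c(z, rep(0, nfft - n)))
      Re(stats::fft(zf * g, inverse = TRUE)[seq_len(n)] / nfft)
    }
    Sxx[j, ] <- sm(Mod(wx)^2) / s
    Syy[j, ] <- sm(Mod(wy)^2) / s
    cr <- wx * Conj(wy)
    zf <- stats::fft(c(cr, rep(0i, nfft - n)))
    Sxy[j, ] <- (stats::fft(zf * g, inverse = TRUE)[seq_len(n)] / nfft) / s
  }
  # boxcar smoothing across scales (0.6 octave)
  win <- max(1L, round(0.6 * config$voices))
  Sxx <- .smooth_scales(Sxx, win)
  Syy <- .smooth_scales(Syy, win)
  SxyR <- .smooth_scales(Re(Sxy), win)
  SxyI <- .smooth_scales(Im(Sxy), win)
  denom <- Sxx * Syy
  coh <- (SxyR^2 + SxyI^2) / pmax(denom, .Machine$double.eps)
  coh[denom <= 0] <- 0
  coh[coh > 1] <- 1
  coh[coh < 0] <- 0

  times <- (seq_len(n) - 1) * dt
  edge <- pmin(times, rev(times))
  coi_scale <- edge / sqrt(2)               # Morlet e-folding time sqrt(2)*s
  coi_period <- ff * coi_scale
  mask <- outer(periods, coi_period, `<=`)
  structure(list(coherence = coh, freqs = 1 / periods, periods = periods,
                 times = times, coi_period = coi_period, coi_mask = mask),
            class = "wavelet_coherence")
}

.smooth_scales <- function(m, win) {
  if (win <= 1L) return(m)
  apply(m, 2, function(col) moving_average(col, win))
}

#' Resize a matrix by nearest-neighbor sampling
#'
#' @param m numeric matrix.
#' @param nr,nc target dimensions.
#' @return `nr x nc` matrix.
#' @export
resize_matrix <- function(m, nr, nc) {
  ri <- pmin(nrow(m), pmax(1L, round(seq(1, nrow(m), length.out = nr))))
  ci <- pmin(ncol(m), pmax(1L, round(seq(1, ncol(m), length.out = nc))))
  m[ri, ci, drop = FALSE]
}

# Build a TFI object from a coherence result.
.tfi_from_coherence <- function(wc, config, event_id = NA, event_time = NA,
                                meta = list()) {
  vals <- wc$coherence
  if (config$apply_coi) vals[!wc$coi_mask] <- 0
  # image convention: high frequencies at the top
  ord <- order(wc$periods)
  img <- resize_matrix(vals[ord, , drop = FALSE],
                       config$image_size, config$image_size)
  structure(list(values = img, event_id = event_id, event_time = event_time,
                 mode = meta$mode %||% NA, encoding = meta$encoding %||% NA,
                 div = meta$div %||% NA, freq_range = range(wc$freqs),
                 size = config$image_size),
            class = "tfi_image")
}

#' @export
print.tfi_image <- function(x, ...) {
  cat(sprintf("<tfi_image> %dx%dx3 | event %s at %.3f s | %s / %s / %s\n",
              x$size, x$size, x$event_id, x$event_time,
              x$mode, x$encoding, x$div))
  invisible(x)
}

#' Efferent and afferent MASP envelopes of a session
#'
#' Computes (and caches on the record) the MASP envelope of the efferent and
#' afferent traces of a session.
#'
#' @param session a `session_record`.
#' @param cwt a [cwt_config()].
#' @return list with `efferent` and `afferent` [masp_series()].
#' @export
session_masp <- function(session, cwt = cwt_config()) {
  if (!is.null(session$masp)) return(session$masp)
  list(
    efferent = compute_masp(session$traces$efferent, session$fs, cwt,
                            electrode = session$meta$efferent_electrode),
    afferent = compute_masp(session$traces$afferent, session$fs, cwt,
                            electrode = session$meta$afferent_electrode)
  )
}

#' Micro-scale TFIs for a session's neurotactile events
#'
#' For each event timestamp, extracts the 300 ms pre / 700 ms post window of
#' both MASP envelopes (decimated to `micro_rate`), computes their wavelet
#' coherence, masks the COI and renders a square TFI. Events whose window is
#' clipped by the session edges are skipped with a message.
#'
#' @param session a `session_record`.
#' @param events data.frame from [detect_events()] (or a numeric vector of
#'   timestamps).
#' @param config a [coherence_config()].
#' @param cwt a [cwt_config()] used for the envelopes.
#' @param masp optional precomputed result of [session_masp()].
#' @return list of `tfi_image` objects.
#' @export
session_tfis <- function(session, events, config = coherence_config(),
                         cwt = cwt_config(), masp = NULL) {
  ts <- if (is.data.frame(events)) events$timestamp_s else as.numeric(events)
  masp <- masp %||% session_masp(session, cwt)
  eff <- decimate_series(masp$efferent$values, masp$efferent$fs,
                         config$micro_rate)
  aff <- decimate_series(masp$afferent$values, masp$afferent$fs,
                         config$micro_rate)
  r <- config$micro_rate
  n <- length(eff)
  meta <- list(mode = session$meta$mode, encoding = session$meta$encoding,
               div = session$meta$div)
  out <- list()
  skipped <- 0L
  for (k in seq_along(ts)) {
    i0 <- round((ts[k] - config$micro_pre) * r) + 1L
    i1 <- i0 + round((config$micro_pre + config$micro_post) * r) - 1L
    if (i0 < 1L || i1 > n) {
      skipped <- skipped + 1L
      next
    }
    wc <- wavelet_coherence(eff[i0:i1], aff[i0:i1], r, config)
    out[[length(out) + 1L]] <-
      .tfi_from_coherence(wc, config, event_id = k, event_time = ts[k],
                          meta = meta)
  }
  if (skipped > 0L)
    message(skipped, " event(s) skipped: window clipped by session edge")
  out
}

#' Single micro-event TFI
#'
#' @param session a `session_record`.
#' @param event_time event timestamp (s).
#' @inheritParams session_tfis
#' @return a `tfi_image`, or `NULL` if the window is clipped.
#' @export
micro_event_tfi <- function(session, event_time, config = coherence_config(),
                            cwt = cwt_config(), masp = NULL) {
  res <- session_tfis(session, event_time, config, cwt, masp)
  if (length(res)) res[[1]] else NULL
}

#' Macro-scale session coherence
#'
#' Decimates both session envelopes to `macro_rate` (anti-aliased), computes
#' their wavelet coherence over the whole session and renders a TFI.
#'
#' @inheritParams session_tfis
#' @param min_freq lowest analyzed frequency (Hz); defaults to 4 periods per
#'   session.
#' @return list with `coherence` (a `wavelet_coherence`) and `tfi`
#'   (a `tfi_image`).
#' @export
macro_session_tfi <- function(session, config = coherence_config(),
                              cwt = cwt_config(), masp = NULL,
                              min_freq = NULL) {
  masp <- masp %||% session_masp(session, cwt)
  eff <- decimate_series(masp$efferent$values, masp$efferent$fs,
                         config$macro_rate)
  aff <- decimate_series(masp$afferent$values, masp$afferent$fs,
                         config$macro_rate)
  wc <- wavelet_coherence(eff, aff, config$macro_rate, config,
                          min_freq = min_freq)
  meta <- list(mode = session$meta$mode, encoding = session$meta$encoding,
               div = session$meta$div)
  list(coherence = wc,
       tfi = .tfi_from_coherence(wc, config, event_id = "macro",
                                 event_time = NA, meta = meta))
}

#' Render a TFI as an RGB array
#'
#' Maps coherence values through a fixed perceptually uniform colormap with
#' color limits 0-1 (no axes or labels), yielding a deterministic
#' `size x size x 3` array in `[0, 1]`.
#'
#' @param tfi a `tfi_image`.
#' @param colormap palette name for `grDevices::hcl.colors`.
#' @return numeric array `size x size x 3`.
#' @export
render_tfi <- function(tfi, colormap = "viridis") {
  pal <- grDevices::hcl.colors(256, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- pmin(256L, pmax(1L, 1L + floor(tfi$values * 255.999)))
  arr <- array(0, dim = c(nrow(tfi$values), ncol(tfi$values), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], nrow(tfi$values))
  arr
}

#' Write a TFI to a PNG file
#'
#' Renders with [render_tfi()] and writes a PNG named
#' `{div}_{mode}_{encoding}_{event:04d}.png` unless a filename is given.
#' Identical TFIs produce byte-identical files.
#'
#' @param tfi a `tfi_image`.
#' @param dir output directory.
#' @param file optional file name override.
#' @param colormap palette name.
#' @return the path written, invisibly.
#' @export
write_tfi_png <- function(tfi, dir = ".", file = NULL, colormap = "viridis") {
  file <- file %||% sprintf("%s_%s_%s_%04d.png", tfi$div, tfi$mode,
                            tfi$encoding,
                            if (is.na(tfi$event_id)) 0L else as.integer(tfi$event_id))
  path <- file.path(dir, file)
  png::writePNG(render_tfi(tfi, colormap), path)
  invisible(path)
}
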