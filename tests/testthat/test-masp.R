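test_that("the power matrix honors its shape and zero contracts", {
  cfg <- cwt_config(n_freqs = 12)
  z <- compute_asp(numeric(4000), 10000, cfg)
  expect_equal(dim(z), c(12, 4000))
  expect_true(all(z == 0))
  expect_error(compute_asp(rnorm(4000), 6000, cfg), "Nyquist")
  expect_error(morlet_cwt(rnorm(10), 10000, 100), "support")
})

test_that("a pure tone peaks at its own frequency band", {
  cfg <- cwt_config(n_freqs = 32)
  fs <- 10000
  t <- seq(0, 0.5, by = 1 / fs)
  x <- sin(2 * pi * 1000 * t)
  asp <- compute_asp(x, fs, cfg)
  freqs <- attr(asp, "freqs")
  # average power over the center (away from edges)
  mid <- 1500:3500
  prof <- rowMeans(asp[, mid])
  f_hat <- freqs[which.max(prof)]
  # within one frequency-resolution step of the log-spaced grid
  step <- freqs[2] / freqs[1]
  expect_lt(abs(log(f_hat / 1000)), 1.5 * log(step))
})

test_that("chunked and single-block transforms agree", {
  set.seed(2)
  x <- rnorm(50000)
  freqs <- exp(seq(log(100), log(4000), length.out = 8))
  w1 <- morlet_cwt(x, 10000, freqs, chunk = 2^20)  # single block
  w2 <- morlet_cwt(x, 10000, freqs, chunk = 2^13)  # many chunks
  mid <- 3000:47000
  expect_lt(max(Mod(w1[, mid] - w2[, mid])), 1e-6 * max(Mod(w1)))
})

test_that("envelope extraction matches a hand-computed toy matrix", {
  cfg <- cwt_config(clip_range = c(0.05, 0.4), clip_mode = "saturate",
                    smooth_ms = 1000)  # 3-sample window at fs = 3
  asp <- matrix(c(
    0.0, 2.0, 10.0, 1.0, 0.0,
    0.1, 3.0,  8.0, 0.5, 0.0,
    0.0, 1.0,  6.0, 0.2, 0.1), nrow = 3, byrow = TRUE)
  # manual: divide by 10, saturate to [0.05, 0.4], column means,
  # 3-point centered moving mean with edge shrinkage, scale to max 1
  sasp <- pmin(pmax(asp / 10, 0.05), 0.4)
  cm <- colMeans(sasp)
  sm <- c(mean(cm[1:2]), mean(cm[1:3]), mean(cm[2:4]), mean(cm[3:5]),
          mean(cm[4:5]))
  manual <- sm / max(sm)
  got <- scale_clip_masp(asp, fs = 3, cfg)
  expect_equal(got$values, manual, tolerance = 1e-12)

  # zero mode: values outside the band are discarded instead
  cfg0 <- cwt_config(clip_range = c(0.05, 0.4), clip_mode = "zero",
                     smooth_ms = 1000)
  sasp0 <- asp / 10
  sasp0[sasp0 < 0.05 | sasp0 > 0.4] <- 0
  cm0 <- colMeans(sasp0)
  sm0 <- c(mean(cm0[1:2]), mean(cm0[1:3]), mean(cm0[2:4]), mean(cm0[3:5]),
           mean(cm0[4:5]))
  expect_equal(scale_clip_masp(asp, fs = 3, cfg0)$values,
               sm0 / max(sm0), tolerance = 1e-12)
})

test_that("degenerate and non-degenerate envelopes normalize correctly", {
  cfg <- cwt_config()
  z <- scale_clip_masp(matrix(0, 4, 100), 1000, cfg)
  expect_true(all(z$values == 0))
  set.seed(7)
  m <- matrix(rexp(400), 4, 100)
  out <- scale_clip_masp(m, 1000, cfg)
  expect_equal(max(out$values), 1)
  expect_true(all(out$values >= 0))
  expect_error(scale_clip_masp(matrix(-1, 2, 2), 1000, cfg), "nonnegative")
})

test_that("peak detection applies the threshold and minimum distance rules", {
  cfg <- cwt_config()
  flat <- masp_series(rep(0.2, 5000), fs = 1000)
  expect_equal(nrow(detect_events(flat, cfg)), 0)

  # two bumps 0.3 s apart: only the taller survives the 0.5 s separation
  t <- seq(0, 5, by = 1e-3)
  v <- 0.9 * exp(-((t - 2.0) / 0.05)^2) + 0.8 * exp(-((t - 2.3) / 0.05)^2)
  ev <- detect_events(masp_series(v, fs = 1000), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$timestamp_s, 2.0, tolerance = 0.02)

  # k well-separated bumps are each recovered near their true time
  centers <- c(1, 2.5, 4, 6, 7.8)
  v2 <- rowSums(sapply(centers, function(c0)
    exp(-((seq(0, 9, 1e-3) - c0) / 0.05)^2)))
  ev2 <- detect_events(masp_series(v2, fs = 1000), cfg)
  expect_equal(nrow(ev2), length(centers))
  expect_equal(ev2$timestamp_s, centers, tolerance = 0.05)
  expect_equal(ev2$iti_s[-1], diff(centers), tolerance = 0.1)
})

test_that("inter-tap intervals are successive differences", {
  expect_equal(compute_iti(c(1, 3, 6)), c(2, 3))
  expect_length(compute_iti(5), 0)
  expect_length(compute_iti(numeric(0)), 0)
  ev <- detect_events(masp_series(rep(0, 100), 100), cwt_config())
  expect_length(compute_iti(ev$timestamp_s), 0)
})

test_that("events shift with the trace and ignore its amplitude", {
  set.seed(31)
  fs <- 10000
  cfg <- cwt_config(n_freqs = 12)
  n <- fs * 4
  tr <- rnorm(n, 0, 15)
  spk <- neurotactile:::spike_template(fs) * 150
  for (t0 in c(1.0, 2.2, 3.1)) {
    for (k in 0:8) {
      i <- round((t0 + k * 0.004) * fs)
      tr[i:(i + length(spk) - 1)] <- tr[i:(i + length(spk) - 1)] + spk
    }
  }
  ev <- detect_events(compute_masp(tr, fs, cfg), cfg)
  # amplitude invariance: positive rescaling leaves the events unchanged
  ev_scaled <- detect_events(compute_masp(3.7 * tr, fs, cfg), cfg)
  expect_equal(ev_scaled$timestamp_s, ev$timestamp_s, tolerance = 1e-9)
  # shift equivariance: a delayed trace shifts all timestamps by the delay
  shift_s <- 0.25
  tr_shift <- c(numeric(shift_s * fs), tr)[seq_len(n)]
  ev_shift <- detect_events(compute_masp(tr_shift, fs, cfg), cfg)
  keep <- ev$timestamp_s + shift_s < 3.5   # events not pushed off the end
  expect_equal(ev_shift$timestamp_s[seq_len(sum(keep))],
               ev$timestamp_s[keep] + shift_s, tolerance = 0.01)
})
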