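test_that("the MEA layout is an 8x8 grid minus corners at 200 um pitch", {
  lay <- mea_layout()
  expect_equal(nrow(lay), 60)
  expect_false(any(lay$row %in% c(1, 8) & lay$col %in% c(1, 8)))
  dx <- sort(unique(diff(sort(unique(lay$x_um)))))
  expect_equal(dx, 200)
  # interior sites have 8 neighbors, edge sites fewer
  expect_length(mea_neighbors(28), 8)
  lay_edge <- lay[lay$row == 1, ][1, "electrode"]
  expect_lt(length(mea_neighbors(lay_edge)), 8)
})

test_that("cultures are reproducible objects that demand a seed", {
  expect_error(build_culture(culture_config()), "seed")
  c1 <- build_culture(culture_config(), seed = 5)
  c2 <- build_culture(culture_config(), seed = 5)
  expect_identical(c1$neurons, c2$neurons)
  expect_identical(c1$weights, c2$weights)
  c3 <- build_culture(culture_config(), seed = 6)
  expect_false(identical(c1$neurons$x_um, c3$neurons$x_um))
  # both selected sites carry neurons
  expect_gt(sum(c1$neurons$efferent), 0)
  expect_gt(sum(c1$neurons$stim_coupling > 0), 0)
})

test_that("silent networks yield noise-only traces within the configured floor", {
  cc <- culture_config(drive_exc = 0, drive_inh = 0, fs = 10000)
  sim <- simulate_culture(cc, NULL, duration = 2, seed = 8, band = NULL)
  expect_equal(nrow(sim$raster), 0)
  for (tr in sim$traces) {
    expect_equal(sd(tr), cc$noise_rms, tolerance = 0.05)
  }
})

test_that("simulation requires a seed and honors channel count and rate", {
  expect_error(simulate_culture(culture_config(), duration = 1), "seed")
  cc <- culture_config(fs = 20000)
  sim <- simulate_culture(cc, NULL, duration = 0.5, seed = 2,
                          electrodes = "all", band = NULL)
  expect_length(sim$traces, 60)
  expect_true(all(vapply(sim$traces, length, numeric(1)) == 0.5 * 20000))
  expect_equal(attr(sim$traces[[1]], "fs"), 20000)
})

test_that("a stimulation pulse evokes the response predicted by a reference integration", {
  # deterministic configuration: no background drive, no recurrence
  cc <- culture_config(drive_exc = 0, drive_inh = 0,
                       connection_probability = 0, fs = 10000,
                       pathway_gain = 0)
  cl <- build_culture(cc, seed = 12)
  st <- stim_trigger_train(c(0.5))
  sim <- simulate_culture(cc, st, duration = 1, seed = 12, band = NULL)
  coupled <- which(cl$neurons$stim_coupling > 0)
  # reference: integrate each coupled neuron with the same split-Euler rule,
  # one 1 ms current pulse of amplitude stim_gain * coupling at t = 0.5 s
  ref_spikes <- integer(0)
  for (i in coupled) {
    nn <- cl$neurons[i, ]
    v <- -65; u <- nn$b * v
    spiked_at <- NA
    for (tick in 1:1000) {
      I <- if (tick == 501) cc$stim_gain * nn$stim_coupling else 0
      for (s in 1:2) {
        vo <- v
        v <- v + 0.5 * (0.04 * vo^2 + 5 * vo + 140 + I - u)
        u <- u + 0.5 * nn$a * (nn$b * vo - u)
        if (v >= 30) {
          v <- nn$c; u <- u + nn$d
          if (is.na(spiked_at)) spiked_at <- tick
        }
      }
    }
    if (!is.na(spiked_at) && spiked_at >= 501 && spiked_at <= 510)
      ref_spikes <- c(ref_spikes, i)
  }
  evoked <- unique(sim$raster$neuron[sim$raster$time_s >= 0.5 &
                                       sim$raster$time_s < 0.51])
  expect_setequal(evoked, ref_spikes)
  expect_gt(length(evoked), 0)
})

test_that("spikes appear strongest at their home electrode", {
  cc <- culture_config(fs = 10000)
  cl <- build_culture(cc, seed = 3)
  # a single spike from an efferent-site neuron
  nid <- which(cl$neurons$efferent)[1]
  raster <- data.frame(neuron = nid, time_s = 0.05)
  nb <- mea_neighbors(cc$efferent_electrode)
  tr <- synthesize_extracellular(raster, cl,
                                 electrodes = c(cc$efferent_electrode, nb),
                                 duration = 0.1, band = NULL, seed = 1)
  # compare template peaks with the noise removed: re-synthesize noiselessly
  cl0 <- cl
  cl0$config$noise_rms <- 1e-9
  tr0 <- synthesize_extracellular(raster, cl0,
                                  electrodes = c(cc$efferent_electrode, nb),
                                  duration = 0.1, band = NULL, seed = 1)
  peak_home <- max(abs(tr0[[as.character(cc$efferent_electrode)]]))
  peak_others <- vapply(as.character(nb), function(e) max(abs(tr0[[e]])),
                        numeric(1))
  expect_gt(peak_home, 2 * max(peak_others))
})

test_that("the online band-pass strongly attenuates sub-100 Hz content", {
  bf <- signal::butter(2, c(100, 3500) / (20000 / 2), type = "pass")
  t <- seq(0, 2, by = 1 / 20000)
  slow <- sin(2 * pi * 10 * t)
  out <- signal::filtfilt(bf, slow)
  atten_db <- 20 * log10(max(abs(out[5000:35000])) / 1)
  expect_lt(atten_db, -20)
  # an empty raster synthesizes to noise only, band-passed
  cc <- culture_config(fs = 20000)
  cl <- build_culture(cc, seed = 9)
  tr <- synthesize_extracellular(data.frame(neuron = integer(0),
                                            time_s = numeric(0)),
                                 cl, duration = 0.25, seed = 2)
  expect_true(all(is.finite(tr[[1]])))
})

test_that("crosstalk exclusion passes by default and fails when gain is doubled", {
  cc <- culture_config(fs = 10000)
  nb <- mea_neighbors(cc$afferent_electrode)
  # vacuous pass with no stimulation
  sim0 <- simulate_culture(cc, NULL, duration = 1, seed = 5,
                           electrodes = c(cc$afferent_electrode, nb))
  ct0 <- verify_no_crosstalk(sim0$traces, numeric(0), 75,
                             cc$afferent_electrode, cc$fs)
  expect_true(ct0$pass)

  st <- stim_trigger_train(seq(0.5, 4.5, by = 0.5))
  sim <- simulate_culture(cc, st, duration = 5, seed = 5,
                          electrodes = c(cc$afferent_electrode, nb))
  ct <- verify_no_crosstalk(sim$traces, sim$stim_times, 75,
                            cc$afferent_electrode, cc$fs)
  expect_true(ct$pass)

  cc2 <- culture_config(fs = 10000, crosstalk_gain = 0.45)
  sim2 <- simulate_culture(cc2, st, duration = 5, seed = 5,
                           electrodes = c(cc2$afferent_electrode, nb))
  ct2 <- verify_no_crosstalk(sim2$traces, sim2$stim_times, 75,
                             cc2$afferent_electrode, cc2$fs)
  expect_false(ct2$pass)
  expect_gt(nrow(ct2$violations), 0)
})

test_that("identical configuration and seed give bit-identical rasters", {
  cc <- culture_config(fs = 10000)
  s1 <- simulate_culture(cc, NULL, duration = 2, seed = 31, band = NULL)
  s2 <- simulate_culture(cc, NULL, duration = 2, seed = 31, band = NULL)
  expect_identical(s1$raster, s2$raster)
})

test_that("stimulation evokes time-locked efferent responses above background", {
  cc <- culture_config(fs = 10000)
  # sparse probe pulses so the evoked response is not masked by the
  # stimulation-driven slow suppression
  st <- stim_trigger_train(seq(1, 19, by = 0.5))
  stim <- simulate_culture(cc, st, duration = 20, seed = 17, band = NULL)
  effn <- which(build_culture(cc, 17)$neurons$efferent)
  r <- stim$raster[stim$raster$neuron %in% effn, ]
  win <- 0.015
  inw <- sum(vapply(st$spike_times, function(t)
    sum(r$time_s > t & r$time_s <= t + win), numeric(1)))
  t_in <- length(st$spike_times) * win
  rate_in <- inw / t_in
  rate_out <- (nrow(r) - inw) / (20 - t_in)
  expect_gt(rate_in, 2 * rate_out)
  # a sustained train recruits the slow suppression current, lowering
  # overall network activity relative to the unstimulated culture --
  # the mechanism behind the encoding effect on tapping intervals
  dense <- stim_trigger_train(seq(0.5, 7.5, by = 0.05))
  spont <- simulate_culture(cc, NULL, duration = 8, seed = 18, band = NULL)
  driven <- simulate_culture(cc, dense, duration = 8, seed = 18, band = NULL)
  expect_lt(nrow(driven$raster), nrow(spont$raster))
})
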