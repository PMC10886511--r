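test_that("input current follows the SA and RA affine maps", {
  g <- encoder_gains()
  expect_equal(compute_input_current(0, 0, g, "SA"), g$beta)
  # RA depends solely on the dynamic channel
  expect_equal(compute_input_current(10, 0, g, "RA"),
               compute_input_current(0, 0, g, "RA"))
  expect_equal(compute_input_current(10, 0, g, "RA"), g$alpha)
  # increments are exactly k_sa * dF_DC + k_ra * dF_AC
  i1 <- compute_input_current(0.2, 1.5, g, "SA")
  i2 <- compute_input_current(0.7, 2.25, g, "SA")
  expect_equal(i2 - i1, g$k_sa * 0.5 + g$k_ra * 0.75)
  expect_error(compute_input_current(NaN, 0, g, "SA"), "rejected input")
  expect_error(compute_input_current(1, Inf, g, "RA"), "rejected input")
})

test_that("RA spike train is invariant to the steady force channel", {
  set.seed(11)
  f_ac <- c(numeric(100), rep(2, 30), numeric(170))
  tr1 <- encode_force_stream(numeric(300), f_ac, mode = "RA")
  tr2 <- encode_force_stream(runif(300, 0, 1), f_ac, mode = "RA")
  expect_identical(tr1$spike_times, tr2$spike_times)
})

test_that("resting fixed point solves the membrane quadratic and is stationary", {
  p <- izhikevich_params()
  st <- izhikevich_fixed_point(p)
  # independent quadratic oracle: X v^2 + (Y - b) v + Z = 0, stable root
  roots <- polyroot(c(p$Z, p$Y - p$b, p$X))
  expect_equal(st$v, min(Re(roots)), tolerance = 1e-10)
  expect_equal(st$u, p$b * st$v, tolerance = 1e-10)
  # state initialized there stays fixed under the integrator
  cur <- st
  for (i in 1:200) cur <- step_neuron(cur, 0, p)$state
  expect_equal(cur$v, st$v, tolerance = 1e-6)
  expect_equal(cur$u, st$u, tolerance = 1e-6)
})

test_that("threshold crossing resets to c, increments u by d and raises 4.5 V", {
  p <- izhikevich_params()
  st <- neuron_state(v = 29.5, u = 0)
  res <- step_neuron(st, 30, p)
  expect_true(res$spiked)
  expect_equal(res$trigger_level, 4.5)
  expect_equal(res$state$v, -65)
  u_after_euler <- 0 + p$dt * p$a * (p$b * 29.5 - 0)
  expect_equal(res$state$u, u_after_euler + p$d)
  # subthreshold step keeps the line at 0 V
  expect_equal(step_neuron(neuron_state(), 0, p)$trigger_level, 0)
})

test_that("default-step inter-spike interval matches a 10x finer integration", {
  isi_at <- function(dt, I) {
    p <- izhikevich_params(dt = dt)
    st <- izhikevich_fixed_point(p)
    times <- numeric(0)
    t <- 0
    for (i in seq_len(round(2000 / dt))) {
      t <- t + dt
      res <- step_neuron(st, I, p)
      st <- res$state
      if (res$spiked) times <- c(times, t)
    }
    mean(diff(times))
  }
  for (I in c(5, 6)) {
    coarse <- isi_at(0.5, I)
    fine <- isi_at(0.05, I)
    expect_lt(abs(coarse - fine) / fine, 0.05)
  }
})

test_that("firing rate is non-decreasing in constant input current", {
  rate_at <- function(I) {
    length(encode_force_stream(rep((I - encoder_gains()$beta) / 20, 3000),
                               numeric(3000), mode = "SA")$spike_times)
  }
  rates <- vapply(c(4, 6, 8, 11, 15, 20), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[length(rates)], rates[1])
})

test_that("force streams encode into SA-tonic / RA-phasic trigger trains", {
  # all-zero stream with subthreshold baselines stays silent
  silent <- encode_force_stream(numeric(4000), numeric(4000), mode = "SA")
  expect_length(silent$spike_times, 0)
  expect_length(encode_force_stream(numeric(10), numeric(10), mode = "RA"), 0)
  expect_length(encode_force_stream(numeric(0), numeric(0), mode = "SA"), 0)

  # rectangular contact: F_DC step with dynamic impulses at the edges
  n <- 3000
  f_dc <- c(numeric(1000), rep(0.2, 1000), numeric(1000))
  f_ac <- abs(c(0, diff(moving_average(f_dc, 5)))) * 1000
  ra <- encode_force_stream(f_dc, f_ac, mode = "RA")
  sa <- encode_force_stream(f_dc, f_ac, mode = "SA")
  # RA spikes cluster at the contact edges only
  edge <- abs(ra$spike_times - 1.0) < 0.05 | abs(ra$spike_times - 2.0) < 0.05
  expect_true(all(edge))
  expect_gt(length(ra$spike_times), 0)
  # SA keeps firing through the hold where RA is silent
  hold <- function(tr) sum(tr$spike_times > 1.1 & tr$spike_times < 1.9)
  expect_gt(hold(sa), hold(ra))
  expect_gt(hold(sa), 10)
  expect_identical(hold(ra), 0L)
  expect_s3_class(sa, "stim_trigger_train")
  expect_equal(sa$trigger_level, 4.5)
})

test_that("trigger trains validate monotonicity and level", {
  expect_error(stim_trigger_train(c(1, 1)), "strictly increasing")
  expect_error(stim_trigger_train(1, trigger_level = 3), "0 or 4.5")
  expect_silent(stim_trigger_train(c(0.1, 0.2), encoding = "RA"))
})

test_that("biphasic pulses are positive-first, charge balanced and refractory", {
  bp <- render_biphasic_pulse(0.01, fs = 20000)
  expect_equal(sum(bp$waveform), 0)
  i0 <- floor(0.01 * 20000) + 1
  expect_gt(bp$waveform[i0], 0)

  # triggers closer than the pulse width: earlier wins, later suppressed;
  # kept set matches a brute-force scan of the min-separation rule
  set.seed(4)
  times <- sort(runif(60, 0, 0.05))
  width <- 2 * 0.5 / 1000
  keep_brute <- logical(60)
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= width) {
      keep_brute[i] <- TRUE
      last <- times[i]
    }
  }
  bp2 <- render_biphasic_pulse(times, fs = 20000, phase_ms = 0.5)
  expect_equal(bp2$kept_times, times[keep_brute])
  expect_equal(length(bp2$kept_times) + length(bp2$suppressed_times), 60)
})

test_that("Euler instability is reported with the step size", {
  p <- izhikevich_params(dt = 40)
  expect_error(
    {
      st <- neuron_state(v = -80, u = -100)
      for (i in 1:50) st <- step_neuron(st, 100, p)$state
    },
    "dt"
  )
})
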