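test_that("input resistance follows Ohm's law on constructed traces", {
  # hand-built trace: -65 mV baseline, exact -8 mV steady step of -80 pA
  dt <- 0.5
  n <- 8001
  t <- (seq_len(n) - 1) * dt
  v <- ifelse(t >= 500 & t < 3500, -73, -65)
  i <- ifelse(t >= 500 & t < 3500, -80, 0)
  s <- sweep(v, i, dt, stimulus_protocol("current_step", onset_ms = 500,
                                         amplitude_pa = -80,
                                         duration_ms = 3000))
  expect_equal(input_resistance(s), 100)
  expect_error(input_resistance(
    sweep(v, i, dt, stimulus_protocol("current_step", onset_ms = 500,
                                      amplitude_pa = 0, duration_ms = 3000))),
    "zero step")
})

test_that("input resistance recovers closed-form values from simulation", {
  s <- make_step_sweep(membrane_params(C = 150, g_L = 5, a = 0, noise_sd = 0))
  expect_equal(input_resistance(s), 200, tolerance = 2 / 200)
  s2 <- make_step_sweep(membrane_params(C = 150, g_L = 5, a = 5, tau_w = 100,
                                        noise_sd = 0))
  expect_equal(input_resistance(s2), 100, tolerance = 2 / 100)
})

test_that("membrane time constant hits the 1 - 1/e crossing", {
  p <- membrane_params(C = 100, g_L = 5, a = 0, noise_sd = 0)  # tau = 20 ms
  s <- make_step_sweep(p)
  expect_equal(membrane_tau(s), 20, tolerance = 0.4 / 20)
  # the fraction of the steady-state change reached at t = tau is ~63%
  t <- sweep_times(s)
  baseline <- mean(s$voltage[t >= 300 & t < 500])
  steady <- mean(s$voltage[t >= 3000 & t < 3500])
  tau_hat <- membrane_tau(s)
  v_at_tau <- s$voltage[which.min(abs(t - (500 + tau_hat)))]
  frac <- (v_at_tau - baseline) / (steady - baseline)
  expect_equal(round(100 * frac), 63)
})

test_that("degenerate instantaneous steps warn but return a bounded tau", {
  dt <- 0.05
  t <- (0:20000) * dt
  v <- ifelse(t >= 500, -73, -65)
  s <- sweep(v, ifelse(t >= 500, -80, 0), dt,
             stimulus_protocol("current_step", onset_ms = 500,
                               amplitude_pa = -80, duration_ms = 500))
  expect_warning(tau <- membrane_tau(s), "measurement warning")
  expect_lte(tau, dt)
})

test_that("sag ratio is 1 for RC membranes and matches the ODE oracle", {
  s <- make_step_sweep(membrane_params(C = 150, g_L = 5, a = 0, noise_sd = 0))
  expect_equal(sag_ratio(s), 1, tolerance = 0.01)

  p <- membrane_params(C = 180, g_L = 10, a = 6, tau_w = 100, noise_sd = 0)
  s2 <- make_step_sweep(p)
  t <- sweep_times(s2)
  vref <- ode_membrane_oracle(p, step_current(500, 3000, -80), t)
  ref_ratio <- (vref[1] - min(vref)) /
    (vref[1] - mean(vref[t >= 3000 & t < 3500]))
  expect_equal(sag_ratio(s2), ref_ratio, tolerance = 0.01)
  expect_error(sag_ratio(make_step_sweep(p, amp = 40)), "hyperpolarizing")
})

test_that("sag is robust to recording noise on average", {
  p0 <- membrane_params(C = 180, g_L = 10, a = 6, tau_w = 100, noise_sd = 0)
  truth <- sag_ratio(make_step_sweep(p0))
  p <- membrane_params(C = 180, g_L = 10, a = 6, tau_w = 100, noise_sd = 0.2)
  vals <- vapply(1:20, function(i) sag_ratio(make_step_sweep(p, seed = i)), 0)
  expect_equal(mean(vals), truth, tolerance = 0.02)
})

test_that("rheobase reads the ramp current at the first spike", {
  p <- membrane_params(C = 150, g_L = 5, E_L = -65, V_T = -42, noise_sd = 0)
  ramp <- stimulus_protocol("current_ramp", onset_ms = 500,
                            slope_pa_per_s = 50, duration_ms = 3000)
  s <- simulate_membrane(p, ramp, 4000, seed = 1)
  spikes <- attr(s, "spike_times")
  expect_gt(length(spikes), 0)
  rb <- rheobase(s)
  expect_equal(rb, 50 * (spikes[1] - 500) / 1000, tolerance = 0.02 * rb)

  # subthreshold ramp: absent marker, not an error
  weak <- stimulus_protocol("current_ramp", onset_ms = 500,
                            slope_pa_per_s = 5, duration_ms = 3000)
  expect_true(is.na(rheobase(simulate_membrane(p, weak, 4000, seed = 1))))
})

test_that("rheobase is stable across noise seeds", {
  p <- membrane_params(C = 150, g_L = 5, E_L = -65, V_T = -42, noise_sd = 0.2)
  ramp <- stimulus_protocol("current_ramp", onset_ms = 500,
                            slope_pa_per_s = 50, duration_ms = 3000)
  r1 <- rheobase(simulate_membrane(p, ramp, 4000, seed = 21))
  r2 <- rheobase(simulate_membrane(p, ramp, 4000, seed = 22))
  expect_lt(abs(r1 - r2), 10)
})

test_that("AP detection finds pasted templates and rejects PSPs", {
  p <- membrane_params(noise_sd = 0)
  s <- simulate_membrane(p, stimulus_protocol("none"), 500, seed = 1)
  expect_equal(nrow(detect_aps(s)), 0)

  # a slow ramp approaches threshold gently: threshold recovered at V_T
  ramp <- stimulus_protocol("current_ramp", onset_ms = 500,
                            slope_pa_per_s = 50, duration_ms = 3000)
  s1 <- simulate_membrane(membrane_params(C = 150, g_L = 5, noise_sd = 0),
                          ramp, 4000, seed = 1)
  ev <- detect_aps(s1)
  expect_gte(nrow(ev), 1)
  expect_equal(ev$threshold_vm[1], -42, tolerance = 0.5)
  expect_lt(abs(ev$threshold_time[1] - attr(s1, "spike_times")[1]), 0.11)

  # five strong pulses at 10 Hz: one event per pulse, peaks at the template
  # peak; detected thresholds sit on the (steep) pulse-driven approach
  n <- floor(1000 / 0.05) + 1
  I5 <- numeric(n)
  for (k in 0:4) I5[(100 + k * 100) / 0.05 + (0:60)] <- 2000
  s5 <- simulate_membrane(p, stimulus_protocol("none"), 1000, seed = 1,
                          current = I5)
  ev5 <- detect_aps(s5)
  expect_equal(nrow(ev5), 5)
  expect_true(all(abs(ev5$threshold_time - attr(s5, "spike_times")) < 2.5))
  expect_equal(ev5$peak_vm, rep(30, 5), tolerance = 1e-6)

  # a large but subthreshold EPSP crosses 1 mV/ms yet peaks below -20 mV
  mb <- membrane_params(C = 150, g_L = 6, a = 0, noise_sd = 0)
  ev_psp <- simulate_evoked(mb, synapse_params(
    epsp_fast = c(amp = 15, rise = 0.5, decay = 8, latency = 3)),
    stimulus_protocol("opto_pulse", onset_ms = 500, pulse_ms = 3),
    n_sweeps = 1, seed = 1, spikes_enabled = FALSE)
  tr <- ev_psp$sweeps[[1]]
  dvdt <- diff(tr$voltage) / tr$time_step
  expect_gt(max(dvdt), 1)  # the derivative criterion alone would fire
  expect_equal(nrow(detect_aps(tr)), 0)
})

test_that("AP amplitude and duration follow the template geometry", {
  p <- membrane_params(C = 150, g_L = 5, V_T = -42, spike_peak = 30,
                       noise_sd = 0)
  ramp <- stimulus_protocol("current_ramp", onset_ms = 500,
                            slope_pa_per_s = 50, duration_ms = 3000)
  s <- simulate_membrane(p, ramp, 4000, seed = 1)
  ev <- detect_aps(s)
  f <- ap_features(ev[1, ], s)
  expect_equal(f$amplitude, 72, tolerance = 0.5)
  expect_gt(f$duration, 0)

  # duration is invariant to a constant offset of the whole trace
  s_off <- s; s_off$voltage <- s$voltage + 7
  ev2 <- detect_aps(s_off)
  f2 <- ap_features(ev2[1, ], s_off)
  expect_equal(f2$duration, f$duration, tolerance = 1e-6)
  expect_equal(f2$amplitude, f$amplitude, tolerance = 1e-6)
})

test_that("impedance spectra match the analytic oracle", {
  p <- membrane_params(C = 150, g_L = 5, a = 0, noise_sd = 0)
  zap <- stimulus_protocol("zap", onset_ms = 0, min_hz = 0.5, max_hz = 20,
                           duration_ms = 20000, amplitude_pa = 15)
  s <- simulate_membrane(p, zap, 20000, seed = 1)
  spec <- impedance_spectrum(s)
  sub <- spec[spec$freq_hz >= 1 & spec$freq_hz <= 20, ]
  za <- analytic_impedance(p, sub$freq_hz)
  expect_lt(max(abs(sub$z_mohm - za) / za), 0.05)
  expect_false(resonance_frequency(spec)$resonant)

  # linearity: doubling the chirp amplitude leaves |Z| unchanged
  zap2 <- stimulus_protocol("zap", onset_ms = 0, min_hz = 0.5, max_hz = 20,
                            duration_ms = 20000, amplitude_pa = 30)
  spec2 <- impedance_spectrum(simulate_membrane(p, zap2, 20000, seed = 1))
  expect_lt(max(abs(spec2$z_mohm - spec$z_mohm) / spec$z_mohm), 0.01)
})

test_that("resonant membranes yield an interior impedance peak", {
  p <- membrane_params(C = 180, g_L = 10, a = 6, tau_w = 100, noise_sd = 0)
  zap <- stimulus_protocol("zap", onset_ms = 0, min_hz = 0.5, max_hz = 20,
                           duration_ms = 20000, amplitude_pa = 40)
  spec <- impedance_spectrum(simulate_membrane(p, zap, 20000, seed = 1))
  rf <- resonance_frequency(spec)
  expect_true(rf$resonant)
  df <- diff(spec$freq_hz[1:2])
  ref <- analytic_resonance(p, band = c(0.5, 20), df = df)
  expect_lte(abs(rf$freq_hz - ref$freq_hz), df + 1e-9)
})

test_that("spiking ZAP sweeps are rejected as contaminated", {
  p <- membrane_params(C = 150, g_L = 5, E_L = -45, V_T = -42, noise_sd = 0)
  zap <- stimulus_protocol("zap", onset_ms = 0, min_hz = 0.5, max_hz = 20,
                           duration_ms = 20000, amplitude_pa = 60)
  s <- simulate_membrane(p, zap, 20000, seed = 1)
  expect_error(impedance_spectrum(s), "contamination")
})

test_that("resonance ties break toward the lower frequency", {
  spec <- data.frame(freq_hz = c(2, 4, 7, 9), z_mohm = c(1, 3, 3, 2),
                     raw = c(1, 3, 3, 2))
  expect_equal(resonance_frequency(spec)$freq_hz, 4)
})

test_that("noiseless parameter recovery holds across random membranes", {
  set.seed(77)
  for (i in 1:12) {
    resonant <- i %% 2 == 0
    p <- random_membrane(resonant = resonant)
    s <- make_step_sweep(p)
    rin_true <- 1000 / (p$g_L + p$a)
    expect_equal(input_resistance(s), rin_true, tolerance = 0.01)
    if (!resonant) {
      expect_equal(membrane_tau(s), p$C / p$g_L, tolerance = 0.02)
      expect_equal(sag_ratio(s), 1, tolerance = 0.01)
    } else {
      expect_gte(sag_ratio(s), 1 - 0.01)
    }
  }
})

test_that("increasing the resonance gain never increases input resistance", {
  rins <- vapply(c(0, 2, 5, 10), function(a) {
    p <- membrane_params(C = 180, g_L = 10, a = a, tau_w = 100, noise_sd = 0)
    input_resistance(make_step_sweep(p))
  }, 0)
  expect_true(all(diff(rins) < 0))
})

test_that("measurements are invariant to constant voltage offsets", {
  p <- membrane_params(C = 180, g_L = 10, a = 6, tau_w = 100, noise_sd = 0)
  s <- make_step_sweep(p)
  s_off <- s; s_off$voltage <- s$voltage + 11
  expect_equal(input_resistance(s_off), input_resistance(s))
  expect_equal(membrane_tau(s_off), membrane_tau(s))
  expect_equal(sag_ratio(s_off), sag_ratio(s))
})
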