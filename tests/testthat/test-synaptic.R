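opto <- stimulus_protocol("opto_pulse", onset_ms = 500, pulse_ms = 3)

evoked_sweeps <- function(amp_e = 0, amp_i_fast = 0, amp_i_slow = 0,
                          lat_e = 3, lat_if = 4.5, lat_is = 8,
                          noise_sd = 0, n_sweeps = 1, seed = 1,
                          membrane = NULL, protocol = opto) {
  mb <- if (is.null(membrane))
    membrane_params(C = 150, g_L = 6, a = 0, noise_sd = noise_sd)
  else membrane
  syn <- synapse_params(
    epsp_fast = c(amp = amp_e, rise = 1, decay = 10, latency = lat_e),
    ipsp_fast = c(amp = -amp_i_fast, rise = 2, decay = 15, latency = lat_if),
    ipsp_slow = c(amp = -amp_i_slow, rise = 50, decay = 200, latency = lat_is))
  simulate_evoked(mb, syn, protocol, n_sweeps = n_sweeps, seed = seed)
}

test_that("baseline excludes the 10 ms immediately before stimulation", {
  s <- sweep(rep(-65, 20001), rep(0, 20001), 0.05, opto)
  expect_equal(baseline_vm(s), -65)

  # a transient confined to the final 10 ms pre-stimulus is ignored
  v <- rep(-65, 20001)
  t <- (0:20000) * 0.05
  v[t >= 492 & t < 500] <- -40
  s2 <- sweep(v, rep(0, 20001), 0.05, opto)
  expect_equal(baseline_vm(s2), -65)

  # trains use a 990 ms window and need 1000 ms of pre-stimulus data
  tr <- stimulus_protocol("opto_train", onset_ms = 1000, frequency_hz = 10,
                          n_pulses = 10, pulse_ms = 3)
  s3 <- sweep(rep(-60, 60001), rep(0, 60001), 0.05, tr)
  expect_equal(baseline_vm(s3), -60)
  early <- stimulus_protocol("opto_pulse", onset_ms = 400, pulse_ms = 3)
  s4 <- sweep(rep(-60, 20001), rep(0, 20001), 0.05, early)
  expect_error(baseline_vm(s4), "window error")
})

test_that("baseline estimator variance shrinks as theory predicts", {
  # the sd of the mean of a 490 ms OU window: var = 2 sd^2 tau/T (T >> tau)
  p <- membrane_params(noise_sd = 0.3, noise_tau = 5)
  n <- floor(1100 / 0.05) + 1
  vals <- vapply(1:100, function(i)
    baseline_vm(simulate_membrane(p, opto, 1100, seed = i,
                                  current = numeric(n))), 0)
  theory_sd <- 0.3 * sqrt(2 * 5 / 490)
  expect_equal(sd(vals), theory_sd, tolerance = 0.35)
})

test_that("sweep averaging is pointwise and validated", {
  s1 <- sweep(rep(-65, 100), rep(0, 100), 0.05, cell_id = "a")
  expect_equal(average_sweeps(list(s1, s1))$voltage, s1$voltage)
  # a sweep and its mirror about baseline average to the baseline
  v <- rnorm(100, 0, 2)
  sa <- sweep(-65 + v, rep(0, 100), 0.05)
  sb <- sweep(-65 - v, rep(0, 100), 0.05)
  expect_equal(average_sweeps(list(sa, sb))$voltage, rep(-65, 100))
  s2 <- sweep(rep(-65, 99), rep(0, 99), 0.05)
  expect_error(average_sweeps(list(s1, s2)), "heterogeneous")
})

test_that("averaging reduces noise roughly as 1/sqrt(n)", {
  p <- membrane_params(noise_sd = 0.5, noise_tau = 5)
  sw <- lapply(1:30, function(i)
    simulate_membrane(p, stimulus_protocol("none"), 2000, seed = i))
  avg <- average_sweeps(sw)
  expect_equal(sd(avg$voltage), 0.5 / sqrt(30), tolerance = 0.4 * 0.5 / sqrt(30))
})

test_that("the E-I ratio formula behaves over its domain", {
  expect_equal(ei_ratio(5, 5), 0.5)
  expect_equal(ei_ratio(5, 0), 1)
  expect_equal(ei_ratio(2, 6), 0.25)
  expect_error(ei_ratio(0, 0), "undefined")
  expect_error(ei_ratio(-1, 2), "magnitudes")
  # strictly decreasing in inhibition at fixed excitation
  vals <- vapply(seq(0, 10, by = 0.5), function(i) ei_ratio(4, i), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("response classification applies the existence floor", {
  expect_equal(classify_response(0, 0), "none")
  expect_equal(classify_response(4, 3), "biphasic")
  expect_equal(classify_response(4, 0.2), "excitatory")
  expect_equal(classify_response(0.3, 2), "inhibitory")
  expect_equal(classify_response(10, 10, suprathreshold = TRUE),
               "suprathreshold")
  # 3 x SE can raise the floor above 0.5 mV
  expect_equal(classify_response(0.8, 0, baseline_se = 0.3), "none")
})

test_that("single-component evoked responses are measured to ~1%", {
  ev <- evoked_sweeps(amp_e = 5)
  m <- measure_evoked(ev$sweeps)
  expect_equal(m$epsp_amp, 5, tolerance = 0.05 / 5)
  expect_equal(m$ipsp_amp, 0)
  expect_equal(m$ei_ratio, 1)
  expect_equal(m$classification, "excitatory")

  ev2 <- evoked_sweeps(amp_i_fast = 3)
  m2 <- measure_evoked(ev2$sweeps)
  expect_equal(m2$ipsp_amp, 3, tolerance = 0.05)
  expect_equal(m2$classification, "inhibitory")
  expect_equal(m2$ei_ratio, 0)
})

test_that("balanced biphasic responses give an E-I ratio near one half", {
  ev <- evoked_sweeps(amp_e = 4, amp_i_fast = 2.4, amp_i_slow = 1.6)
  m <- measure_evoked(ev$sweeps)
  expect_equal(m$classification, "biphasic")
  # temporal overlap shrinks the two components asymmetrically, so the
  # measured ratio sits near, not exactly at, balance
  expect_lt(abs(m$ei_ratio - 0.5), 0.06)
})

test_that("latency and half-width are withheld below 1 mV", {
  m <- measure_evoked(evoked_sweeps(amp_e = 0.8)$sweeps)
  expect_true(is.na(m$latency_ms))
  expect_true(is.na(m$half_width_ms))
  m2 <- measure_evoked(evoked_sweeps(amp_e = 2)$sweeps)
  expect_false(is.na(m2$latency_ms))
  expect_false(is.na(m2$half_width_ms))
})

test_that("latency tracks the simulated synaptic delay", {
  lats <- vapply(c(2, 4, 6, 8), function(d)
    measure_evoked(evoked_sweeps(amp_e = 4, lat_e = d)$sweeps)$latency_ms, 0)
  expect_true(all(diff(lats) > 0))
  expect_equal(diff(lats), rep(2, 3), tolerance = 0.1)
})

test_that("measured latency matches an independent superposition oracle", {
  mb <- membrane_params(C = 150, g_L = 6, a = 0, noise_sd = 0)
  syn <- synapse_params(
    epsp_fast = c(amp = 4, rise = 1, decay = 10, latency = 3))
  m <- measure_evoked(simulate_evoked(mb, syn, opto, n_sweeps = 1,
                                      seed = 1)$sweeps)
  v <- superposition_oracle(mb, syn, 500, 1100, 0.05)
  t <- (seq_along(v) - 1) * 0.05
  peak <- max(v - mb$E_L)
  lat_ref <- t[which(v - mb$E_L >= 0.1 * peak)[1]] - 500
  expect_equal(m$latency_ms, lat_ref, tolerance = 0.5)
})

test_that("suprathreshold responses dominate classification", {
  mb <- membrane_params(C = 150, g_L = 6, a = 0, E_L = -65, V_T = -52,
                        noise_sd = 0)
  ev <- evoked_sweeps(amp_e = 20, membrane = mb)
  m <- measure_evoked(ev$sweeps)
  expect_equal(m$classification, "suprathreshold")
  expect_true(is.na(m$ei_ratio))
})

test_that("train measurement uses contiguous inter-pulse windows", {
  tr10 <- stimulus_protocol("opto_train", onset_ms = 1000, frequency_hz = 10,
                            n_pulses = 10, pulse_ms = 3)
  mb <- membrane_params(C = 150, g_L = 6, a = 0, noise_sd = 0)
  syn_flat <- synapse_params(
    epsp_fast = c(amp = 3, rise = 1, decay = 10, latency = 3),
    ipsp_fast = c(amp = -2, rise = 2, decay = 15, latency = 4.5))
  ev <- simulate_evoked(mb, syn_flat, tr10, n_sweeps = 1, seed = 1)
  m <- measure_train(ev$sweeps)
  expect_equal(nrow(m), 10)
  expect_equal(unique(m$frequency_hz), 10)
  # constant kernels: pulse 1 and pulse 10 agree within summation tolerance
  expect_equal(m$epsp_amp[10], m$epsp_amp[1],
               tolerance = 0.05 * m$epsp_amp[1])

  # growing inhibition: larger pulse-10 IPSP, smaller pulse-10 E-I
  syn_grow <- synapse_params(
    epsp_fast = c(amp = 3, rise = 1, decay = 10, latency = 3),
    ipsp_fast = c(amp = -2, rise = 2, decay = 15, latency = 4.5),
    train_scaling = list(epsp_fast = rep(1, 10),
                         ipsp_fast = seq(1, 1.6, length.out = 10)))
  mg <- measure_train(simulate_evoked(mb, syn_grow, tr10, n_sweeps = 1,
                                      seed = 1)$sweeps)
  expect_gt(mg$ipsp_amp[10], mg$ipsp_amp[1])
  expect_lt(mg$ei_ratio[10], mg$ei_ratio[1])
})

test_that("20 Hz trains use 50 ms windows", {
  tr20 <- stimulus_protocol("opto_train", onset_ms = 1000, frequency_hz = 20,
                            n_pulses = 10, pulse_ms = 3)
  # fast membrane (tau = 5 ms) so responses decay fully within each window
  mb <- membrane_params(C = 60, g_L = 12, a = 0, noise_sd = 0)
  # an EPSP confined to the first 40 ms of each window must not leak into the
  # next pulse's measurement
  syn <- synapse_params(
    epsp_fast = c(amp = 3, rise = 0.5, decay = 4, latency = 2))
  ev <- simulate_evoked(mb, syn, tr20, n_sweeps = 1, seed = 1)
  m <- measure_train(ev$sweeps)
  expect_equal(nrow(m), 10)
  # pulse onsets sit at 1000 + k*50: all windows capture the same kernel
  expect_equal(m$epsp_amp, rep(m$epsp_amp[1], 10), tolerance = 0.05)

  # a sweep too short for the final window errors
  short <- simulate_evoked(mb, syn, tr20, n_sweeps = 1, seed = 1,
                           duration_ms = 1460)
  expect_error(measure_train(short$sweeps), "truncation")
})

test_that("paired recordings detect inhibitory connections", {
  pre <- membrane_params(C = 100, g_L = 8, E_L = -60, V_T = -45, noise_sd = 0)
  pp <- stimulus_protocol("paired_ap", onset_ms = 600, amplitude_na = 1.5,
                          pulse_ms = 3)
  pre_sw <- simulate_membrane(pre, pp, 1500, seed = 1)
  spk <- attr(pre_sw, "spike_times")[1]
  post_mb <- membrane_params(C = 150, g_L = 6, a = 0, noise_sd = 0.1)
  mk_post <- function(amp_fast, amp_slow, seed) {
    syn <- synapse_params(
      epsp_fast = c(amp = 0, rise = 1, decay = 10, latency = 1),
      ipsp_fast = c(amp = amp_fast, rise = 2, decay = 15, latency = 2),
      ipsp_slow = c(amp = amp_slow, rise = 50, decay = 200, latency = 4))
    op2 <- stimulus_protocol("opto_pulse", onset_ms = spk, pulse_ms = 3)
    simulate_evoked(post_mb, syn, op2, n_sweeps = 10, seed = seed,
                    duration_ms = 1500)$sweeps
  }
  res <- paired_connectivity(pre_sw, mk_post(-1.5, 0, 2))
  expect_true(res$connected)
  expect_equal(res$ipsp_amp, 1.5, tolerance = 0.12)

  # no kernel: not connected
  res0 <- paired_connectivity(pre_sw, mk_post(0, 0, 3))
  expect_false(res0$connected)

  # adding a slow component broadens the IPSP
  fast_only <- paired_connectivity(pre_sw, mk_post(-1.5, 0, 4))
  both <- paired_connectivity(pre_sw, mk_post(-1.5, -1.0, 4))
  expect_gt(both$half_width_ms, fast_only$half_width_ms)

  flat <- sweep(rep(-60, 30001), rep(0, 30001), 0.05, cell_id = "pre")
  expect_error(paired_connectivity(flat, mk_post(0, 0, 5)),
               "no presynaptic spike")
})

test_that("condition contrasts build paired long tables", {
  base <- data.frame(cell_id = paste0("c", 1:5), epsp_amp = 1:5,
                     ipsp_amp = 5:1, half_width_ms = seq(10, 30, 5))
  same <- base
  tab <- condition_contrast(list(baseline = base, drug = same))
  expect_equal(nrow(tab), 2 * 3 * 5)
  wide <- tab[tab$feature == "epsp_amp", ]
  d <- wide$value[wide$condition == "baseline"] -
    wide$value[wide$condition == "drug"]
  expect_equal(d, rep(0, 5))

  three <- condition_contrast(list(a = base, b = base, c = base))
  expect_equal(sum(three$feature == "epsp_amp"), 15)
  expect_error(condition_contrast(list(a = base)), "2 conditions")
  other <- base; other$cell_id <- paste0("x", 1:5)
  expect_error(condition_contrast(list(a = base, b = other)),
               "no overlapping")
})

test_that("blocking fast inhibition broadens the EPSP in noiseless cells", {
  cfg <- default_cohort_config(noise_sd = 0)
  cfg$classes$L2_SC$n <- 4
  cfg$classes$L2_SC$mixture <- list(biphasic = 1.0)
  cfg$classes$L2_PC$n <- 2
  cfg$classes$L2_PC$mixture <- list(biphasic = 1.0)
  cfg$n_sweeps <- 1
  cfg$amp_floor_mV <- 2.5
  cfg$ei_clip <- c(0.45, 0.85)
  gen <- generate_cohort(cfg, seed = 5, simulate_sweeps = FALSE)
  gt <- gen$ground_truth
  for (i in seq_len(nrow(gt))) {
    m_base <- measure_evoked(simulate_cell_sweeps(gt[i, ], cfg, "opto_pulse",
                                                  seed = 1)[[1]] |> list())
    m_gbz <- measure_evoked(simulate_cell_sweeps(gt[i, ], cfg, "opto_pulse",
                                                 condition = "gabazine_cgp",
                                                 seed = 1)[[1]] |> list())
    expect_gt(m_gbz$half_width_ms, m_base$half_width_ms)
  }
})

test_that("classification recovers ground truth on a labelled cohort", {
  cfg <- default_cohort_config(noise_sd = 0.2)
  cfg$classes$L2_SC$n <- 30
  cfg$classes$L2_PC$n <- 15
  gen <- generate_cohort(cfg, seed = 8, simulate_sweeps = FALSE)
  gt <- gen$ground_truth
  cls <- vapply(seq_len(nrow(gt)), function(i) {
    sw <- simulate_cell_sweeps(gt[i, ], cfg, "opto_pulse",
                               seed = (8 + 104729 * i) %% 2147483647)
    measure_evoked(sw)$classification
  }, "")
  expect_gte(mean(cls == gt$response_class), 0.95)
})

test_that("response tabulation reports counts and percentages", {
  tb <- tabulate_responses(c(rep("biphasic", 58), rep("excitatory", 27),
                             rep("inhibitory", 5)))
  expect_equal(tb$n[tb$classification == "biphasic"], 58)
  expect_equal(round(tb$pct[tb$classification == "biphasic"], 1), 64.4)
  expect_equal(round(responder_pct(127, 158), 1), 80.4)
  expect_error(responder_pct(5, 0), "invalid")
})
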