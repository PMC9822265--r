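# Seeded simulator of subthreshold-resonant membranes and synaptic responses.
#
# Membrane model: a two-state linear (resonate-and-fire style) membrane,
#   C dV/dt = -g_L (V - E_L) - a w + I(t) + noise
#   tau_w dw/dt = (V - E_L) - w
# with a stereotyped action-potential template pasted when V crosses V_T.
# The resonance current a*w produces sag on hyperpolarising steps and a
# band-pass impedance when a > 0 and tau_w exceeds the membrane time constant.
# Integration uses the exact matrix-exponential propagator per sample, so the
# subthreshold response to piecewise-constant input is exact.

DEFAULT_DT <- 0.05  # ms per sample (20 kHz)

#' Membrane parameters for the simulator
#'
#' @param C membrane capacitance, pF (> 0).
#' @param g_L leak conductance, nS (> 0). The membrane time constant is
#'   `C / g_L` ms and the zero-frequency input resistance is
#'   `1000 / (g_L + a)` MOhm.
#' @param E_L leak reversal (resting) potential, mV.
#' @param a resonance-current gain, nS (>= 0); `a = 0` gives a pure RC cell.
#' @param tau_w resonance-current time constant, ms (> 0).
#' @param V_T spike threshold, mV (> `E_L`).
#' @param V_r post-spike reset, mV.
#' @param spike_peak,spike_rise,spike_fall stereotyped action-potential
#'   template: peak voltage (mV) and rise/fall times (ms).
#' @param noise_sd stationary standard deviation of Ornstein-Uhlenbeck
#'   recording noise added to the voltage trace, mV.
#' @param noise_tau correlation time of the noise, ms.
#' @return an object of class `membrane_params`.
#' @export
membrane_params <- function(C = 150, g_L = 5, E_L = -65, a = 0, tau_w = 100,
                            V_T = -42, V_r = -65, spike_peak = 30,
                            spike_rise = 0.6, spike_fall = 1.2,
                            noise_sd = 0, noise_tau = 5) {
  if (C <= 0 || g_L <= 0 || tau_w <= 0) stop("C, g_L, tau_w must be > 0")
  if (a < 0) stop("a must be >= 0")
  if (V_T <= E_L) stop("V_T must exceed E_L")
  structure(list(C = C, g_L = g_L, E_L = E_L, a = a, tau_w = tau_w,
                 V_T = V_T, V_r = V_r, spike_peak = spike_peak,
                 spike_rise = spike_rise, spike_fall = spike_fall,
                 noise_sd = noise_sd, noise_tau = noise_tau),
            class = "membrane_params")
}

# System matrix for the (V - E_L, w) pair.
membrane_matrix <- function(p) {
  matrix(c(-p$g_L / p$C, 1 / p$tau_w, -p$a / p$C, -1 / p$tau_w), 2, 2)
}

# Exact propagator E = expm(A dt) and input matrix M = A^-1 (E - I), via the
# eigendecomposition (complex eigenvalues allowed; result is real). A
# degenerate (repeated-eigenvalue) system is perturbed infinitesimally.
propagators <- function(p, dt) {
  A <- membrane_matrix(p)
  eg <- eigen(A)
  if (abs(eg$values[1] - eg$values[2]) < 1e-12 * max(abs(eg$values))) {
    A[2, 2] <- A[2, 2] * (1 + 1e-9)
    eg <- eigen(A)
  }
  P <- eg$vectors
  Pi <- solve(P)
  E <- Re(P %*% diag(exp(eg$values * dt)) %*% Pi)
  M <- Re(P %*% diag((exp(eg$values * dt) - 1) / eg$values) %*% Pi)
  list(E = E, M = M)
}

spike_template_wave <- function(p, dt) {
  n_rise <- max(1L, round(p$spike_rise / dt))
  n_fall <- max(1L, round(p$spike_fall / dt))
  t_r <- seq_len(n_rise) / n_rise
  t_f <- seq_len(n_fall) / n_fall
  c(p$V_T + (p$spike_peak - p$V_T) * sin(pi * t_r / 2),
    p$V_r + (p$spike_peak - p$V_r) * cos(pi * t_f / 2))
}

# Stationary OU noise, exact AR(1) discretisation.
ou_noise <- function(n, sd, tau, dt) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-dt / tau)
  eps <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  eps[1] <- rnorm(1, 0, sd)
  as.numeric(filter(eps, phi, method = "recursive"))
}

#' Command-current waveform for a protocol
#'
#' @param protocol a [stimulus_protocol()] of kind `current_step`,
#'   `current_ramp`, `zap`, `paired_ap` or `none`.
#' @param n number of samples.
#' @param dt sampling interval, ms.
#' @return numeric vector of injected current, pA.
#' @export
protocol_current <- function(protocol, n, dt) {
  t <- (seq_len(n) - 1L) * dt
  I <- numeric(n)
  pr <- protocol$parameters
  on <- protocol$onset_ms
  switch(protocol$kind,
    none = I,
    current_step = {
      idx <- t >= on & t < on + pr$duration_ms
      I[idx] <- pr$amplitude_pa
      I
    },
    current_ramp = {
      idx <- t >= on & t < on + pr$duration_ms
      I[idx] <- pr$slope_pa_per_s * (t[idx] - on) / 1000
      I
    },
    zap = {
      idx <- t >= on & t < on + pr$duration_ms
      tt <- (t[idx] - on) / 1000                       # seconds
      Tz <- pr$duration_ms / 1000
      phase <- 2 * pi * (pr$min_hz * tt +
                           (pr$max_hz - pr$min_hz) * tt^2 / (2 * Tz))
      I[idx] <- pr$amplitude_pa * sin(phase)
      I
    },
    paired_ap = {
      idx <- t >= on & t < on + pr$pulse_ms
      I[idx] <- pr$amplitude_na * 1000
      I
    },
    stop("protocol_current does not generate currents for kind ",
         protocol$kind))
}

# Light-pulse onset times for opto protocols, ms.
opto_onsets <- function(protocol) {
  pr <- protocol$parameters
  if (protocol$kind == "opto_pulse") return(protocol$onset_ms)
  if (protocol$kind == "opto_train")
    return(protocol$onset_ms + (seq_len(pr$n_pulses) - 1L) *
             1000 / pr$frequency_hz)
  stop("not an opto protocol")
}

#' Simulate a current-clamp sweep
#'
#' Deterministic given `seed`. With zero noise and no input the trace sits at
#' `E_L`; subthreshold responses are exact for piecewise-constant input.
#'
#' @param params a [membrane_params()].
#' @param protocol a [stimulus_protocol()] handled by [protocol_current()].
#' @param duration_ms sweep duration, ms (must cover the protocol).
#' @param seed integer seed for the noise.
#' @param dt sampling interval, ms.
#' @param spikes_enabled paste spike templates on threshold crossing.
#' @param current optional explicit current vector (pA) overriding the
#'   protocol waveform (used for synaptic kernels).
#' @param cell_id,sweep_index,condition sweep metadata.
#' @return a [sweep()]; true threshold-crossing times (ms) are stored in
#'   `attr(, "spike_times")`.
#' @export
simulate_membrane <- function(params, protocol, duration_ms, seed = 1L,
                              dt = DEFAULT_DT, spikes_enabled = TRUE,
                              current = NULL, cell_id = "sim",
                              sweep_index = 0L, condition = "baseline") {
  n <- floor(duration_ms / dt) + 1L
  pdur <- protocol$onset_ms +
    sum(unlist(protocol$parameters[names(protocol$parameters) %in%
                                     c("duration_ms")]))
  if (protocol$kind %in% c("opto_pulse", "opto_train")) {
    pdur <- max(opto_onsets(protocol)) + protocol$parameters$pulse_ms
  }
  if (pdur > duration_ms)
    stop("argument error: protocol longer than sweep duration")
  I <- if (is.null(current)) protocol_current(protocol, n, dt) else current
  if (length(I) != n) stop("current vector length mismatch")
  pp <- propagators(params, dt)
  res <- gif_integrate_cpp(I, dt, pp$E, pp$M, params$C, params$E_L, 0, 0,
                           spikes_enabled, params$V_T, params$V_r,
                           spike_template_wave(params, dt))
  v <- res$voltage
  if (params$noise_sd > 0) {
    set.seed(seed %% .Machine$integer.max)
    v <- v + ou_noise(n, params$noise_sd, params$noise_tau, dt)
  }
  out <- sweep(v, I, dt, protocol, cell_id = cell_id,
               sweep_index = sweep_index, condition = condition)
  attr(out, "spike_times") <- res$spike_times
  out
}

#' Analytic subthreshold impedance magnitude
#'
#' Closed-form impedance of the linearised membrane,
#' `Z(w) = (1 + i w tau_w) / ((g_L + i w C)(1 + i w tau_w) + a)`,
#' used as the oracle for the ZAP-based resonance measurement. At zero
#' frequency it equals `1 / (g_L + a)`; with `a = 0` it is monotonically
#' decreasing in frequency.
#'
#' @param params a [membrane_params()].
#' @param freq_hz frequencies, Hz (>= 0); vectorised.
#' @return impedance magnitudes, MOhm.
#' @export
analytic_impedance <- function(params, freq_hz) {
  if (any(freq_hz < 0)) stop("argument error: negative frequency")
  w <- 2 * pi * freq_hz / 1000                      # rad/ms
  z <- (1 + 1i * w * params$tau_w) /
    ((params$g_L + 1i * w * params$C) * (1 + 1i * w * params$tau_w) +
       params$a)
  1000 * Mod(z)                                     # GOhm -> MOhm
}

#' Frequency of maximal analytic impedance
#'
#' @param params a [membrane_params()].
#' @param band frequency band searched, Hz.
#' @param df grid spacing, Hz.
#' @return list with `freq_hz` (argmax) and `resonant` (FALSE when the
#'   maximum sits at the lower band edge).
#' @export
analytic_resonance <- function(params, band = c(0.5, 20), df = 0.01) {
  f <- seq(band[1], band[2], by = df)
  z <- analytic_impedance(params, f)
  i <- which.max(z)
  list(freq_hz = f[i], resonant = i > 1L)
}

# ---- synaptic kernels ------------------------------------------------------

SYNAPSE_COMPONENTS <- c("epsp_fast", "epsp_slow", "ipsp_fast", "ipsp_slow")

#' Synaptic response parameters
#'
#' Each component (AMPA-like and NMDA-like excitation; GABA_A-like fast and
#' GABA_B-like slow inhibition) is a difference-of-exponentials current kernel
#' calibrated so that, alone on the subthreshold membrane, its somatic peak
#' equals the specified amplitude. Inhibitory latencies exceed the excitatory
#' latency, reflecting the disynaptic feedforward path.
#'
#' @param epsp_fast,epsp_slow,ipsp_fast,ipsp_slow per component:
#'   `c(amp, rise, decay, latency)` - somatic peak amplitude in mV (signed:
#'   >= 0 for excitatory, <= 0 for inhibitory), rise and decay time constants
#'   in ms (decay > rise), and synaptic latency in ms from stimulus onset.
#'   Use `NULL` or zero amplitude to omit a component.
#' @param train_scaling multiplicative per-pulse factors applied to each
#'   component's amplitude during train stimulation; a list with one numeric
#'   vector per component name, or a single vector recycled to all components.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(epsp_fast = c(amp = 0, rise = 1, decay = 10,
                                         latency = 3),
                           epsp_slow = NULL,
                           ipsp_fast = c(amp = 0, rise = 2, decay = 15,
                                         latency = 4.5),
                           ipsp_slow = c(amp = 0, rise = 50, decay = 200,
                                         latency = 8),
                           train_scaling = NULL) {
  comps <- list(epsp_fast = epsp_fast, epsp_slow = epsp_slow,
                ipsp_fast = ipsp_fast, ipsp_slow = ipsp_slow)
  comps <- comps[!vapply(comps, is.null, TRUE)]
  for (nm in names(comps)) {
    co <- comps[[nm]]
    if (!all(c("amp", "rise", "decay", "latency") %in% names(co)))
      stop("component ", nm, " needs amp, rise, decay, latency")
    if (co[["rise"]] <= 0 || co[["decay"]] <= co[["rise"]])
      stop("component ", nm, ": need 0 < rise < decay")
    if (grepl("^epsp", nm) && co[["amp"]] < 0)
      stop("excitatory amplitude must be >= 0")
    if (grepl("^ipsp", nm) && co[["amp"]] > 0)
      stop("inhibitory amplitude must be <= 0")
  }
  if (!is.null(comps$ipsp_fast) && !is.null(comps$epsp_fast) &&
      comps$ipsp_fast[["amp"]] < 0 &&
      comps$ipsp_fast[["latency"]] <= comps$epsp_fast[["latency"]])
    stop("ipsp_fast latency must exceed epsp_fast latency")
  if (!is.null(train_scaling) && !is.list(train_scaling))
    train_scaling <- setNames(rep(list(train_scaling), length(comps)),
                              names(comps))
  structure(list(components = comps, train_scaling = train_scaling),
            class = "synapse_params")
}

# Unit-peak difference-of-exponentials kernel sampled at dt, truncated where
# it falls below 1e-5 of peak (capped at 1.5 s).
psp_kernel <- function(rise, decay, dt) {
  tmax <- min(1500, decay * 12)
  t <- seq(0, tmax, by = dt)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Peak somatic voltage deflection (mV per pA of kernel peak current) of one
# kernel on the subthreshold membrane; used for amplitude calibration.
kernel_gain <- function(params, rise, decay, dt) {
  k <- psp_kernel(rise, decay, dt)
  n <- length(k) + round(4 * decay / dt)
  I <- c(k, numeric(n - length(k)))
  pp <- propagators(params, dt)
  res <- gif_integrate_cpp(I, dt, pp$E, pp$M, params$C, params$E_L, 0, 0,
                           FALSE, params$V_T, params$V_r, numeric(1))
  max(abs(res$voltage - params$E_L))
}

# Full injected-current waveform for an opto protocol given calibrated
# component kernels and per-pulse scaling.
evoked_current <- function(params, synapse, protocol, n, dt) {
  onsets <- opto_onsets(protocol)
  n_pulses <- length(onsets)
  I <- numeric(n)
  for (nm in names(synapse$components)) {
    co <- synapse$components[[nm]]
    if (co[["amp"]] == 0) next
    gain <- kernel_gain(params, co[["rise"]], co[["decay"]], dt)
    k <- psp_kernel(co[["rise"]], co[["decay"]], dt) * co[["amp"]] / gain
    scal <- if (!is.null(synapse$train_scaling) &&
                !is.null(synapse$train_scaling[[nm]]))
      synapse$train_scaling[[nm]] else rep(1, n_pulses)
    if (length(scal) != n_pulses)
      stop("argument error: train scaling length (", length(scal),
           ") != pulse count (", n_pulses, ")")
    for (j in seq_len(n_pulses)) {
      i0 <- round((onsets[j] + co[["latency"]]) / dt) + 1L
      if (i0 > n) next
      len <- min(length(k), n - i0 + 1L)
      idx <- i0:(i0 + len - 1L)
      I[idx] <- I[idx] + scal[j] * k[seq_len(len)]
    }
  }
  I
}

#' Simulate optogenetically evoked responses
#'
#' Each synaptic component injects a calibrated difference-of-exponentials
#' current so that, alone and noiselessly, its somatic peak equals the
#' specified amplitude. Train protocols apply per-pulse scaling factors.
#'
#' @param membrane a [membrane_params()].
#' @param synapse a [synapse_params()].
#' @param protocol an `opto_pulse` or `opto_train` [stimulus_protocol()].
#' @param n_sweeps number of repeat sweeps (independent noise).
#' @param seed integer seed.
#' @param duration_ms sweep duration; defaults to onset + 600 ms for single
#'   pulses and the last pulse window + 200 ms for trains.
#' @param dt sampling interval, ms.
#' @param spikes_enabled paste spike templates on threshold crossing.
#' @param cell_id,condition sweep metadata.
#' @return list with `sweeps` (list of [sweep()]) and `ground_truth` (the
#'   realised component amplitudes and latencies).
#' @export
simulate_evoked <- function(membrane, synapse, protocol, n_sweeps = 3L,
                            seed = 1L, duration_ms = NULL, dt = DEFAULT_DT,
                            spikes_enabled = TRUE, cell_id = "sim",
                            condition = "baseline") {
  if (!protocol$kind %in% c("opto_pulse", "opto_train"))
    stop("argument error: protocol must be opto_pulse or opto_train")
  if (is.null(duration_ms)) {
    onsets <- opto_onsets(protocol)
    duration_ms <- if (protocol$kind == "opto_pulse")
      protocol$onset_ms + 600 else
        max(onsets) + 1000 / protocol$parameters$frequency_hz + 200
  }
  n <- floor(duration_ms / dt) + 1L
  I <- evoked_current(membrane, synapse, protocol, n, dt)
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    simulate_membrane(membrane, protocol, duration_ms,
                      seed = (seed + 7919L * i) %% .Machine$integer.max,
                      dt = dt, spikes_enabled = spikes_enabled, current = I,
                      cell_id = cell_id, sweep_index = i - 1L,
                      condition = condition)
  })
  gt <- do.call(rbind, lapply(names(synapse$components), function(nm) {
    co <- synapse$components[[nm]]
    data.frame(component = nm, amp_mV = unname(co[["amp"]]),
               rise_ms = unname(co[["rise"]]), decay_ms = unname(co[["decay"]]),
               latency_ms = unname(co[["latency"]]))
  }))
  list(sweeps = sweeps, ground_truth = gt)
}
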