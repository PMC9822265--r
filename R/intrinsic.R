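# Sub- and suprathreshold intrinsic properties from step, ramp and ZAP sweeps.
#
# Window conventions (3 s steps): baseline = mean over the 200 ms preceding
# stimulus onset; steady state = mean over the last 500 ms of the step.

STEP_BASELINE_MS <- 200
STEP_STEADY_MS <- 500
TAU_FRACTION <- 1 - exp(-1)  # 0.6321; the "~63%" criterion

step_params <- function(s) {
  if (s$protocol$kind != "current_step")
    stop("argument error: expected a current_step sweep")
  list(on = s$protocol$onset_ms,
       dur = s$protocol$parameters$duration_ms,
       amp = s$protocol$parameters$amplitude_pa)
}

window_mean <- function(s, from, to) {
  t <- sweep_times(s)
  mean(s$voltage[t >= from & t < to])
}

step_levels <- function(s) {
  p <- step_params(s)
  list(baseline = window_mean(s, p$on - STEP_BASELINE_MS, p$on),
       steady = window_mean(s, p$on + p$dur - STEP_STEADY_MS, p$on + p$dur),
       p = p)
}

check_no_spikes <- function(s, from, to, what) {
  ev <- detect_aps(s)
  if (nrow(ev) && any(ev$threshold_time >= from & ev$threshold_time <= to))
    stop("contamination error: spike detected during ", what)
}

#' Input resistance from a hyperpolarizing current step
#'
#' Steady-state voltage change from baseline divided by the injected current
#' amplitude.
#'
#' @param s a `current_step` [sweep()] (step duration >= 1 s, amplitude != 0).
#' @return input resistance, MOhm (positive).
#' @export
input_resistance <- function(s) {
  lv <- step_levels(s)
  if (lv$p$amp == 0) stop("argument error: zero step amplitude")
  if (lv$p$dur < 1000) stop("argument error: step shorter than 1 s")
  if (lv$p$amp < 0)
    check_no_spikes(s, lv$p$on - STEP_BASELINE_MS, lv$p$on + lv$p$dur,
                    "hyperpolarizing-step measurement window")
  abs((lv$steady - lv$baseline) / lv$p$amp) * 1000  # mV/pA = GOhm -> MOhm
}

#' Membrane time constant from a current step
#'
#' Time from step onset at which the voltage change first reaches
#' 63.21% (1 - 1/e) of its steady-state value, with linear interpolation
#' between samples.
#'
#' @param s a `current_step` [sweep()].
#' @return time constant, ms. A degenerate (quasi-instantaneous) rise returns
#'   a value bounded by the sampling interval with a warning.
#' @export
membrane_tau <- function(s) {
  lv <- step_levels(s)
  target <- lv$baseline + TAU_FRACTION * (lv$steady - lv$baseline)
  t <- sweep_times(s)
  idx <- which(t >= lv$p$on & t < lv$p$on + lv$p$dur)
  v <- s$voltage[idx]
  sgn <- sign(lv$steady - lv$baseline)
  hit <- which(sgn * v >= sgn * target)
  if (!length(hit)) stop("voltage never reaches the 63% criterion")
  i <- hit[1]
  if (i <= 2L)
    warning("measurement warning: 63% reached within 2 samples of onset")
  if (i == 1L) return(t[idx[1]] - lv$p$on + s$time_step)
  # interpolate between samples i-1 and i
  v0 <- v[i - 1L]; v1 <- v[i]
  frac <- if (v1 == v0) 0 else (target - v0) / (v1 - v0)
  (t[idx[i - 1L]] + frac * s$time_step) - lv$p$on
}

#' Sag ratio from a hyperpolarizing current step
#'
#' Ratio of the maximum voltage decrease to the steady-state decrease; 1 for
#' a non-sagging (monotone) response, > 1 when a resonance/h-type current
#' produces a depolarising rebound during the step.
#'
#' The trough is taken on a 25 ms-smoothed copy of the trace: the sag trough
#' evolves on the resonance-current timescale (tens of ms), so smoothing
#' leaves the noiseless trough essentially unchanged while suppressing the
#' extreme-value bias that recording noise would otherwise add to the minimum.
#'
#' @param s a hyperpolarizing `current_step` [sweep()].
#' @param trough_smooth_ms boxcar width used for the trough, ms.
#' @return sag ratio (dimensionless, >= 1 up to measurement tolerance).
#' @export
sag_ratio <- function(s, trough_smooth_ms = 25) {
  lv <- step_levels(s)
  if (lv$p$amp >= 0) stop("argument error: sag needs a hyperpolarizing step")
  if (lv$baseline - lv$steady < 0.5)
    stop("indeterminate error: steady-state change < 0.5 mV")
  t <- sweep_times(s)
  sm <- smooth_1ms(s$voltage, s$time_step, width_ms = trough_smooth_ms)
  vmin <- min(sm[t >= lv$p$on & t < lv$p$on + lv$p$dur])
  (lv$baseline - vmin) / (lv$baseline - lv$steady)
}

#' Rheobase from a depolarizing current ramp
#'
#' Injected current at the time of the first detected action potential,
#' `slope * (t_spike - onset)`.
#'
#' @param s a `current_ramp` [sweep()].
#' @return rheobase, pA, or `NA` when no spike occurs during the ramp.
#' @export
rheobase <- function(s) {
  if (s$protocol$kind != "current_ramp")
    stop("argument error: expected a current_ramp sweep")
  ev <- detect_aps(s)
  on <- s$protocol$onset_ms
  dur <- s$protocol$parameters$duration_ms
  ev <- ev[ev$threshold_time >= on & ev$threshold_time <= on + dur, ,
           drop = FALSE]
  if (!nrow(ev)) return(NA_real_)
  s$protocol$parameters$slope_pa_per_s * (ev$threshold_time[1] - on) / 1000
}

#' Detect action potentials
#'
#' Threshold is the first sample within each suprathreshold excursion at which
#' the centred-difference derivative exceeds 1 mV/ms; to reject fast synaptic
#' potentials an event must additionally reach a peak of at least -20 mV
#' within 2 ms. Candidates within 2 ms of an accepted threshold (or before the
#' voltage falls back below it) are grouped into one event.
#'
#' @param s a [sweep()].
#' @param dvdt_crit derivative criterion, mV/ms.
#' @param peak_floor minimum peak voltage, mV.
#' @return data frame with `threshold_time` (ms), `threshold_vm` (mV),
#'   `peak_time` (ms), `peak_vm` (mV); zero rows when no spikes.
#' @export
detect_aps <- function(s, dvdt_crit = 1, peak_floor = -20) {
  v <- s$voltage
  n <- length(v)
  dt <- s$time_step
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  cand <- which(dvdt > dvdt_crit)
  look <- max(1L, round(2 / dt))
  out <- list()
  i_ptr <- 1L
  while (i_ptr <= length(cand)) {
    i <- cand[i_ptr]
    win <- i:min(n, i + look)
    pk <- which.max(v[win])
    if (v[win[pk]] >= peak_floor) {
      thr_v <- v[i]
      # the excursion runs until the voltage returns to (or below) its
      # threshold; the event peak is the maximum over the whole excursion,
      # not just the 2 ms acceptance window
      after <- which(v[(i + 1L):n] <= thr_v)
      iend <- if (length(after)) i + after[1] else n
      ip <- i - 1L + which.max(v[i:iend])
      out[[length(out) + 1L]] <- c(threshold_time = (i - 1L) * dt,
                                   threshold_vm = thr_v,
                                   peak_time = (ip - 1L) * dt,
                                   peak_vm = v[ip])
      skip_to <- max(iend, i + look)
      i_ptr <- i_ptr + 1L
      while (i_ptr <= length(cand) && cand[i_ptr] <= skip_to)
        i_ptr <- i_ptr + 1L
    } else {
      i_ptr <- i_ptr + 1L
    }
  }
  if (!length(out))
    return(data.frame(threshold_time = numeric(), threshold_vm = numeric(),
                      peak_time = numeric(), peak_vm = numeric()))
  as.data.frame(do.call(rbind, out))
}

#' Action-potential amplitude and duration
#'
#' Amplitude is the voltage change from threshold to peak; duration is the
#' width of the spike at the threshold voltage (threshold-to-threshold, with
#' linear interpolation at the downward crossing).
#'
#' @param event one row of the [detect_aps()] table.
#' @param s the [sweep()] the event was detected in.
#' @return list with `amplitude` (mV) and `duration` (ms).
#' @export
ap_features <- function(event, s) {
  v <- s$voltage
  dt <- s$time_step
  amp <- event$peak_vm - event$threshold_vm
  ip <- round(event$peak_time / dt) + 1L
  below <- which(v[(ip + 1L):length(v)] < event$threshold_vm)
  if (!length(below))
    stop("truncation error: trace ends before downward threshold crossing")
  j <- ip + below[1]                       # first sample below threshold
  v0 <- v[j - 1L]; v1 <- v[j]
  frac <- if (v1 == v0) 0 else (v0 - event$threshold_vm) / (v0 - v1)
  t_down <- (j - 2L + frac) * dt
  list(amplitude = amp, duration = t_down - event$threshold_time)
}

#' Impedance spectrum from a ZAP (chirp) sweep
#'
#' `|Z|(f) = |FFT(V - mean V)| / |FFT(I - mean I)|`, restricted to the chirp
#' band, smoothed with a 0.5 Hz boxcar and reported on frequency bins of the
#' same width (so the spectral resolution matches the smoothing bandwidth).
#' The full-resolution unsmoothed spectrum is attached as
#' `attr(, "raw_spectrum")`.
#'
#' @param s a `zap` [sweep()] with no spikes.
#' @param smooth_hz boxcar full width, Hz.
#' @param bin_hz reported bin width, Hz (defaults to `smooth_hz`).
#' @return data frame with `freq_hz` (bin centres), `z_mohm` (smoothed),
#'   `raw` (bin-averaged unsmoothed magnitude).
#' @export
impedance_spectrum <- function(s, smooth_hz = 0.5, bin_hz = smooth_hz) {
  if (s$protocol$kind != "zap")
    stop("argument error: expected a zap sweep")
  if (nrow(detect_aps(s)))
    stop("contamination error: spikes present in ZAP sweep")
  pr <- s$protocol$parameters
  # trim to a 2-3-5-smooth length so the FFT stays O(n log n)
  n <- smooth_length(length(s$voltage))
  v <- s$voltage[seq_len(n)]
  cur <- s$current[seq_len(n)]
  fs <- 1000 / s$time_step                 # Hz
  freq <- (seq_len(n) - 1L) * fs / n
  Zf <- Mod(fft(v - mean(v))) / Mod(fft(cur - mean(cur)))
  keep <- freq >= pr$min_hz & freq <= pr$max_hz
  if (!any(keep)) stop("argument error: empty analysis band")
  f <- freq[keep]
  raw <- 1000 * Zf[keep]                   # mV/pA = GOhm -> MOhm
  df <- fs / n
  k <- max(1L, round(smooth_hz / df))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(filter(raw, rep(1 / k, k), sides = 2))
  # shrink the boxcar at the band edges instead of dropping bins
  half <- (k - 1L) %/% 2L
  for (i in which(is.na(sm))) {
    h <- min(half, i - 1L, length(raw) - i)
    sm[i] <- mean(raw[(i - h):(i + h)])
  }
  # aggregate onto bin_hz-wide bins
  bin <- floor((f - pr$min_hz) / bin_hz)
  centres <- pr$min_hz + (unique(bin) + 0.5) * bin_hz
  out <- data.frame(
    freq_hz = centres,
    z_mohm = as.numeric(tapply(sm, bin, mean)),
    raw = as.numeric(tapply(raw, bin, mean)))
  attr(out, "raw_spectrum") <- data.frame(freq_hz = f, z_mohm = sm,
                                          raw = raw)
  out
}

# largest integer <= n whose prime factors are all in {2, 3, 5}
smooth_length <- function(n) {
  for (m in n:2) {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
  }
  n
}

#' Resonance frequency from an impedance spectrum
#'
#' Frequency of the global maximum of the smoothed impedance magnitude; ties
#' break toward the lower frequency. A maximum at the band's lower edge is
#' flagged non-resonant (low-pass membrane).
#'
#' @param spectrum output of [impedance_spectrum()].
#' @return list with `freq_hz` and logical `resonant`.
#' @export
resonance_frequency <- function(spectrum) {
  if (!nrow(spectrum)) stop("argument error: empty spectrum")
  z <- spectrum$z_mohm
  i <- which(z >= max(z) - 1e-12 * abs(max(z)))[1]  # tie -> lower frequency
  list(freq_hz = spectrum$freq_hz[i], resonant = i > 1L)
}

#' Full intrinsic profile of one cell
#'
#' Convenience wrapper combining the individual measurements from a
#' hyperpolarizing step, a depolarizing ramp and a ZAP sweep.
#'
#' @param step_sweep hyperpolarizing `current_step` [sweep()].
#' @param ramp_sweep `current_ramp` [sweep()] or `NULL`.
#' @param zap_sweep `zap` [sweep()] or `NULL`.
#' @return one-row data frame mirroring the intrinsic-profile fields.
#' @export
intrinsic_profile <- function(step_sweep, ramp_sweep = NULL,
                              zap_sweep = NULL) {
  lv <- step_levels(step_sweep)
  res <- data.frame(cell_id = step_sweep$cell_id,
                    resting_vm = lv$baseline,
                    input_resistance = input_resistance(step_sweep),
                    tau_m = membrane_tau(step_sweep),
                    sag_ratio = sag_ratio(step_sweep),
                    rheobase = NA_real_, ap_threshold = NA_real_,
                    ap_amplitude = NA_real_, ap_duration = NA_real_,
                    resonance_freq = NA_real_, resonant = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(ramp_sweep)) {
    res$rheobase <- rheobase(ramp_sweep)
    ev <- detect_aps(ramp_sweep)
    if (nrow(ev)) {
      feats <- ap_features(ev[1, ], ramp_sweep)
      res$ap_threshold <- ev$threshold_vm[1]
      res$ap_amplitude <- feats$amplitude
      res$ap_duration <- feats$duration
    }
  }
  if (!is.null(zap_sweep)) {
    rf <- resonance_frequency(impedance_spectrum(zap_sweep))
    res$resonance_freq <- rf$freq_hz
    res$resonant <- rf$resonant
  }
  res
}
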