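# Measurement and classification of optogenetically evoked responses.
#
# Amplitudes are read off the averaged trace after a centred 1 ms mean;
# baselines exclude the 10 ms immediately before stimulation. The E-I ratio is
# EPSP / (EPSP + |IPSP|), in [0, 1].

EVOKED_WINDOW_MS <- 500        # post-stimulus search window, single pulse
EXISTENCE_FLOOR_MV <- 0.5      # minimum detectable component amplitude
PSP_REPORT_FLOOR_MV <- 1       # latency/half-width reported above this
SUPRA_WINDOW_MS <- 50          # AP within this of onset => suprathreshold

RESPONSE_CLASSES <- c("none", "suprathreshold", "excitatory", "inhibitory",
                      "biphasic")

#' Pre-stimulus baseline membrane potential
#'
#' Mean of the voltage over a 490 ms window before stimulation (990 ms for
#' trains), excluding the 10 ms immediately prior to stimulus onset.
#'
#' @param s a [sweep()] (or averaged sweep).
#' @param protocol the governing [stimulus_protocol()]; defaults to the
#'   sweep's own.
#' @return baseline membrane potential, mV.
#' @export
baseline_vm <- function(s, protocol = s$protocol) {
  span <- if (protocol$kind == "opto_train") 1000 else 500
  on <- protocol$onset_ms
  if (on < span)
    stop("window error: need ", span, " ms of pre-stimulus recording")
  window_mean(s, on - span, on - 10)
}

# Noise level of the averaged trace: sd of the baseline-window samples. Used
# as the standard error of the averaged baseline for existence tests.
baseline_se <- function(s, protocol = s$protocol) {
  span <- if (protocol$kind == "opto_train") 1000 else 500
  on <- protocol$onset_ms
  t <- sweep_times(s)
  sd(s$voltage[t >= on - span & t < on - 10])
}

#' Pointwise average of repeat sweeps
#'
#' @param sweeps list of [sweep()] objects with equal length, time step and
#'   protocol kind.
#' @return a [sweep()] holding the mean trace; `attr(, "n_averaged")` records
#'   the sweep count.
#' @export
average_sweeps <- function(sweeps) {
  if (!length(sweeps)) stop("argument error: no sweeps")
  n <- length(sweeps[[1]]$voltage)
  dt <- sweeps[[1]]$time_step
  kind <- sweeps[[1]]$protocol$kind
  for (s in sweeps)
    if (length(s$voltage) != n || s$time_step != dt ||
        s$protocol$kind != kind)
      stop("argument error: heterogeneous sweeps")
  v <- rowMeans(vapply(sweeps, `[[`, numeric(n), "voltage"))
  i <- rowMeans(vapply(sweeps, `[[`, numeric(n), "current"))
  out <- sweep(v, i, dt, sweeps[[1]]$protocol,
               cell_id = sweeps[[1]]$cell_id,
               condition = sweeps[[1]]$condition)
  attr(out, "n_averaged") <- length(sweeps)
  out
}

# Centred 1 ms rolling mean (edges shrink symmetrically).
smooth_1ms <- function(v, dt, width_ms = 1) {
  k <- max(1L, round(width_ms / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(v)
  sm <- as.numeric(filter(v, rep(1 / k, k), sides = 2))
  half <- (k - 1L) %/% 2L
  for (i in which(is.na(sm))) {
    h <- min(half, i - 1L, length(v) - i)
    sm[i] <- mean(v[(i - h):(i + h)])
  }
  sm
}

#' Excitation-inhibition ratio
#'
#' `epsp / (epsp + ipsp)` with both amplitudes as non-negative magnitudes:
#' 1 = pure excitation, 0 = pure inhibition, 0.5 = balanced.
#'
#' @param epsp_amp EPSP peak amplitude, mV (>= 0).
#' @param ipsp_amp IPSP peak magnitude, mV (>= 0).
#' @return ratio in `[0, 1]`.
#' @export
ei_ratio <- function(epsp_amp, ipsp_amp) {
  if (any(epsp_amp < 0) || any(ipsp_amp < 0))
    stop("argument error: amplitudes must be magnitudes (>= 0)")
  tot <- epsp_amp + ipsp_amp
  if (any(tot == 0)) stop("undefined-value error: both amplitudes zero")
  epsp_amp / tot
}

#' Classify an evoked response
#'
#' Suprathreshold dominates. Otherwise a component exists when its amplitude
#' reaches `max(0.5 mV, 3 x SE of the averaged baseline)`; both components
#' give `biphasic`, one gives `excitatory`/`inhibitory`, neither gives `none`.
#'
#' @param epsp_amp,ipsp_amp component magnitudes, mV (>= 0).
#' @param suprathreshold did any individual sweep spike within 50 ms of onset?
#' @param baseline_se standard error of the averaged baseline, mV.
#' @return one of `"none"`, `"suprathreshold"`, `"excitatory"`,
#'   `"inhibitory"`, `"biphasic"`.
#' @export
classify_response <- function(epsp_amp, ipsp_amp, suprathreshold = FALSE,
                              baseline_se = 0) {
  stopifnot(epsp_amp >= 0, ipsp_amp >= 0)
  if (suprathreshold) return("suprathreshold")
  floor_mv <- max(EXISTENCE_FLOOR_MV, 3 * baseline_se)
  e <- epsp_amp >= floor_mv
  i <- ipsp_amp >= floor_mv
  if (e && i) "biphasic" else if (e) "excitatory" else if (i) "inhibitory"
  else "none"
}

# Peak/trough extraction with EPSP-before-IPSP ordering on a smoothed,
# baseline-subtracted trace restricted to the response window.
find_extrema <- function(dv, floor_mv) {
  i_max <- which.max(dv)
  i_min <- which.min(dv)
  e <- max(dv[i_max], 0)
  i <- max(-dv[i_min], 0)
  if (e >= floor_mv && i >= floor_mv && i_max > i_min) {
    # enforce ordering: seek the EPSP peak before the trough, then the trough
    # after that peak
    i_max <- which.max(dv[seq_len(i_min)])
    e <- max(dv[i_max], 0)
    if (e >= floor_mv) {
      rest <- i_max:length(dv)
      i_min <- i_max - 1L + which.min(dv[rest])
      i <- max(-dv[i_min], 0)
    } else {
      i_max <- which.max(dv)
      e <- max(dv[i_max], 0)
    }
  }
  list(epsp = e, ipsp = i, i_peak = i_max, i_trough = i_min)
}

# 10%-rise latency of the governing (first/larger) component.
deviation_latency <- function(dv, t_rel, amp, sgn) {
  thr <- 0.1 * amp
  hit <- which(sgn * dv >= thr)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(t_rel[1])
  f <- (thr - sgn * dv[i - 1L]) / (sgn * dv[i] - sgn * dv[i - 1L])
  t_rel[i - 1L] + f * (t_rel[i] - t_rel[i - 1L])
}

# width at 50% of the governing peak, linear interpolation
half_width_ms <- function(dv, t_rel, i_ext, sgn) {
  y <- sgn * dv
  half <- y[i_ext] / 2
  left <- which(y[seq_len(i_ext)] < half)
  right <- which(y[i_ext:length(y)] < half)
  if (!length(left) || !length(right)) return(NA_real_)
  il <- max(left)
  t_l <- t_rel[il] + (half - y[il]) / (y[il + 1L] - y[il]) *
    (t_rel[il + 1L] - t_rel[il])
  ir <- i_ext - 1L + min(right)
  t_r <- t_rel[ir - 1L] + (y[ir - 1L] - half) / (y[ir - 1L] - y[ir]) *
    (t_rel[ir] - t_rel[ir - 1L])
  t_r - t_l
}

#' Measure a single-pulse evoked response
#'
#' On the averaged trace: EPSP amplitude is the maximal 1 ms-mean
#' depolarisation from baseline within 500 ms of stimulus onset (floored at
#' zero), IPSP amplitude the analogous hyperpolarisation magnitude; when both
#' exist the EPSP peak is sought before the IPSP trough. Latency is the time
#' from onset to a 10% deviation from baseline of the governing component and
#' the half-width is measured at 50% of its peak; both are reported only when
#' that amplitude reaches 1 mV. A response is suprathreshold when any
#' individual sweep spikes within 50 ms of onset.
#'
#' @param sweeps list of repeat [sweep()]s with an `opto_pulse` protocol.
#' @param window_ms post-stimulus search window, ms.
#' @return one-row data frame: `cell_id`, `condition`, `baseline_vm`,
#'   `epsp_amp`, `ipsp_amp`, `latency_ms`, `half_width_ms`, `classification`,
#'   `ei_ratio`, `n_sweeps_averaged`.
#' @export
measure_evoked <- function(sweeps, window_ms = EVOKED_WINDOW_MS) {
  if (!length(sweeps)) stop("argument error: no sweeps")
  avg <- average_sweeps(sweeps)
  prot <- avg$protocol
  if (prot$kind != "opto_pulse")
    stop("argument error: expected opto_pulse sweeps")
  on <- prot$onset_ms
  bl <- baseline_vm(avg, prot)
  se <- baseline_se(avg, prot)
  t <- sweep_times(avg)
  sm <- smooth_1ms(avg$voltage, avg$time_step)
  win <- which(t > on & t <= on + window_ms)
  if (!length(win)) stop("argument error: empty response window")
  dv <- sm[win] - bl
  t_rel <- t[win] - on
  floor_mv <- max(EXISTENCE_FLOOR_MV, 3 * se)
  ex <- find_extrema(dv, floor_mv)

  supra <- any(vapply(sweeps, function(s) {
    ev <- detect_aps(s)
    nrow(ev) > 0 && any(ev$threshold_time >= on &
                          ev$threshold_time <= on + SUPRA_WINDOW_MS)
  }, TRUE))

  cls <- classify_response(ex$epsp, ex$ipsp, supra, se)
  # governing component: the excitatory peak when present, else the trough
  gov_amp <- if (ex$epsp > 0) ex$epsp else ex$ipsp
  gov_sgn <- if (ex$epsp > 0) 1 else -1
  gov_idx <- if (ex$epsp > 0) ex$i_peak else ex$i_trough
  lat <- hw <- NA_real_
  if (!is.na(gov_amp) && gov_amp >= PSP_REPORT_FLOOR_MV) {
    lat <- deviation_latency(dv, t_rel, gov_amp, gov_sgn)
    hw <- half_width_ms(dv, t_rel, gov_idx, gov_sgn)
  }
  ei <- if (cls %in% c("none", "suprathreshold") ||
            (ex$epsp + ex$ipsp) == 0) NA_real_ else ei_ratio(ex$epsp, ex$ipsp)
  data.frame(cell_id = avg$cell_id, condition = avg$condition,
             baseline_vm = bl, epsp_amp = ex$epsp, ipsp_amp = ex$ipsp,
             latency_ms = lat, half_width_ms = hw, classification = cls,
             ei_ratio = ei, n_sweeps_averaged = length(sweeps),
             stringsAsFactors = FALSE)
}

#' Measure per-pulse responses to a 10/20 Hz train
#'
#' Against a single train-level baseline (990 ms pre-stimulus window), the
#' peak depolarisation and hyperpolarisation are taken within each inter-pulse
#' window: `[onset_k, onset_k + 1000/frequency)` ms, i.e. 100 ms windows at
#' 10 Hz and 50 ms at 20 Hz.
#'
#' @param sweeps list of repeat [sweep()]s with an `opto_train` protocol.
#' @return data frame with one row per pulse: `cell_id`, `pulse`, `epsp_amp`,
#'   `ipsp_amp`, `ei_ratio`, plus `baseline_vm` and `frequency_hz`.
#' @export
measure_train <- function(sweeps) {
  avg <- average_sweeps(sweeps)
  prot <- avg$protocol
  if (prot$kind != "opto_train")
    stop("argument error: expected opto_train sweeps")
  f <- prot$parameters$frequency_hz
  onsets <- opto_onsets(prot)
  wlen <- 1000 / f
  if (max(onsets) + wlen > sweep_duration(avg))
    stop("truncation error: final pulse window extends past sweep end")
  bl <- baseline_vm(avg, prot)
  t <- sweep_times(avg)
  sm <- smooth_1ms(avg$voltage, avg$time_step)
  out <- lapply(seq_along(onsets), function(k) {
    idx <- which(t >= onsets[k] & t < onsets[k] + wlen)
    dv <- sm[idx] - bl
    e <- max(c(dv, 0))
    i <- max(c(-dv, 0))
    data.frame(cell_id = avg$cell_id, pulse = k, epsp_amp = e, ipsp_amp = i,
               ei_ratio = if (e + i > 0) e / (e + i) else NA_real_,
               baseline_vm = bl, frequency_hz = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Connectivity from a paired recording
#'
#' Tests whether an action potential evoked in the presynaptic cell
#' hyperpolarises the simultaneously recorded postsynaptic cell. The pair is
#' connected when the averaged postsynaptic trace hyperpolarises by at least
#' `max(0.1 mV, 3 x SE of baseline)` within 50 ms of the presynaptic spike.
#' Half-width is computed on the single average of all sweeps.
#'
#' @param pre_sweep presynaptic [sweep()] containing the evoked spike.
#' @param post_sweeps list of postsynaptic [sweep()]s (repeats).
#' @return one-row data frame: `pre_cell`, `post_cell`, `connected`,
#'   `ipsp_amp`, `half_width_ms`, `spike_time`.
#' @export
paired_connectivity <- function(pre_sweep, post_sweeps) {
  ev <- detect_aps(pre_sweep)
  if (!nrow(ev)) stop("argument error: no presynaptic spike found")
  t_spk <- ev$threshold_time[1]
  avg <- average_sweeps(post_sweeps)
  t <- sweep_times(avg)
  span <- min(490, t_spk - 10)
  if (span <= 0) stop("window error: no pre-spike baseline available")
  bl <- mean(avg$voltage[t >= t_spk - 10 - span & t < t_spk - 10])
  se <- sd(avg$voltage[t >= t_spk - 10 - span & t < t_spk - 10])
  sm <- smooth_1ms(avg$voltage, avg$time_step)
  win <- which(t > t_spk & t <= t_spk + 50)
  dv <- sm[win] - bl
  depth <- max(c(-dv, 0))
  floor_mv <- max(0.1, 3 * se)
  connected <- depth >= floor_mv
  hw <- NA_real_
  if (connected) {
    # measure on a longer window so slow components are not clipped
    win2 <- which(t > t_spk & t <= min(max(t), t_spk + 500))
    dv2 <- sm[win2] - bl
    i_tr <- which.min(dv2)
    depth <- -dv2[i_tr]
    hw <- half_width_ms(dv2, t[win2] - t_spk, i_tr, -1)
  }
  data.frame(pre_cell = pre_sweep$cell_id, post_cell = avg$cell_id,
             connected = connected, ipsp_amp = if (connected) depth else 0,
             half_width_ms = hw, spike_time = t_spk,
             stringsAsFactors = FALSE)
}

#' Long-format feature table across pharmacological conditions
#'
#' Reshapes per-cell evoked measurements from two or more conditions into a
#' long table of (cell, condition, feature, value) rows, keeping only cells
#' present in every condition - ready for a Friedman test across three or more
#' conditions or a paired Wilcoxon test for two.
#'
#' @param responses_by_condition named list (condition -> data frame from
#'   [measure_evoked()], one row per cell).
#' @param features columns to carry.
#' @return long data frame with `cell_id`, `condition`, `feature`, `value`.
#' @export
condition_contrast <- function(responses_by_condition,
                               features = c("epsp_amp", "ipsp_amp",
                                            "half_width_ms")) {
  if (length(responses_by_condition) < 2L)
    stop("argument error: need >= 2 conditions")
  ids <- Reduce(intersect,
                lapply(responses_by_condition, function(d) d$cell_id))
  if (!length(ids)) stop("argument error: no overlapping cells")
  out <- list()
  for (cond in names(responses_by_condition)) {
    d <- responses_by_condition[[cond]]
    d <- d[match(ids, d$cell_id), , drop = FALSE]
    for (ft in features)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = ids, condition = cond, feature = ft, value = d[[ft]],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Tabulate response classifications
#'
#' @param classification character vector of per-cell response classes.
#' @return data frame with `classification`, `n`, `pct` (percentage of all
#'   cells, 1 dp scale preserved as raw numeric).
#' @export
tabulate_responses <- function(classification) {
  tb <- table(factor(classification, levels = RESPONSE_CLASSES))
  data.frame(classification = names(tb), n = as.integer(tb),
             pct = 100 * as.integer(tb) / length(classification),
             stringsAsFactors = FALSE)
}

#' Responder proportion
#'
#' Fraction of cells showing any evoked response (class other than `"none"`),
#' as a percentage.
#'
#' @param n_responders,n_total counts.
#' @return percentage (0-100).
#' @export
responder_pct <- function(n_responders, n_total) {
  if (n_total <= 0 || n_responders < 0 || n_responders > n_total)
    stop("argument error: invalid counts")
  100 * n_responders / n_total
}
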