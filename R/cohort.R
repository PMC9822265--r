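# Seeded generation of synthetic recording cohorts with ground truth. The
# generator emulates the study design: per-class cell counts, response-class
# mixtures, excitation-inhibition ratio distributions (pyramidal cells biased
# to excitation, stellate cells heterogeneous), mediolateral/dorsoventral
# position assignments, and growth of inhibition across 10/20 Hz trains for
# stellate cells.

#' Default cohort configuration
#'
#' Defaults reproduce the reported layer-2 responder structure: 90 stellate
#' cells with a 58/27/5 biphasic/excitatory/inhibitory mixture and 37
#' pyramidal cells with a 21/16 biphasic/excitatory mixture; E-I ratio draws
#' centred at 0.558 (SC) and 0.759 (PC) with concentrations matched to the
#' reported interquartile ranges; stellate-cell inhibition grows across
#' 10 Hz trains while pyramidal-cell scaling stays near unity.
#'
#' @param noise_sd recording-noise standard deviation, mV.
#' @return nested list accepted by [generate_cohort()].
#' @export
default_cohort_config <- function(noise_sd = 0.2) {
  list(
    classes = list(
      L2_SC = list(
        n = 90,
        mixture = list(biphasic = 58 / 90, excitatory = 27 / 90,
                       inhibitory = 5 / 90),
        epsp_meanlog = log(3), epsp_sdlog = 0.4,
        ipsp_meanlog = log(2), ipsp_sdlog = 0.4,
        ei_mean = 0.558, ei_conc = 10,
        ipsp_fast_frac = 0.6,
        train_growth = c(1.0, 2.5),
        membrane = list(C = 200, g_L = 12, a = 5, tau_w = 100,
                        jitter = 0.12)),
      L2_PC = list(
        n = 37,
        mixture = list(biphasic = 21 / 37, excitatory = 16 / 37),
        epsp_meanlog = log(5), epsp_sdlog = 0.4,
        ipsp_meanlog = log(2), ipsp_sdlog = 0.4,
        ei_mean = 0.759, ei_conc = 14,
        ipsp_fast_frac = 0.6,
        train_growth = c(0.9, 1.1),
        membrane = list(C = 150, g_L = 6, a = 1, tau_w = 80,
                        jitter = 0.12))),
    latency = list(epsp_mean = 3.1, epsp_sd = 0.4,
                   ipsp_fast_delay = 1.5, ipsp_slow_delay = 5),
    kinetics = list(epsp = c(rise = 1, decay = 10),
                    ipsp_fast = c(rise = 2, decay = 15),
                    ipsp_slow = c(rise = 50, decay = 200)),
    position = list(ml_range = c(0, 900), dv_range = c(2.8, 4.2)),
    resting = list(mean = -65, sd = 3),
    series_res_range = c(15, 45),
    noise_sd = noise_sd, noise_tau = 5,
    n_sweeps = 10,
    opto = list(onset_ms = 500, pulse_ms = 3),
    train = list(onset_ms = 1000, frequency_hz = 10, n_pulses = 10,
                 pulse_ms = 3),
    amp_floor_mV = 1.0, ei_clip = c(0.10, 0.88))
}

# deterministic class counts from mixture weights (largest remainder)
mixture_counts <- function(weights, n) {
  w <- unlist(weights)
  if (abs(sum(w) - 1) > 1e-9)
    stop("config error: mixture weights must sum to 1")
  raw <- w * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  setNames(as.integer(cnt), names(w))
}

draw_cell <- function(cls_name, cls, resp_class, cfg) {
  floor_mv <- cfg$amp_floor_mV
  epsp <- ipsp <- 0
  if (resp_class %in% c("biphasic", "excitatory", "suprathreshold"))
    epsp <- max(rlnorm(1, cls$epsp_meanlog, cls$epsp_sdlog), floor_mv)
  if (resp_class == "biphasic") {
    r <- rbeta(1, cls$ei_mean * cls$ei_conc, (1 - cls$ei_mean) * cls$ei_conc)
    r <- min(max(r, cfg$ei_clip[1]), cfg$ei_clip[2])
    ipsp <- max(epsp * (1 - r) / r, floor_mv)
  } else if (resp_class == "inhibitory") {
    ipsp <- max(rlnorm(1, cls$ipsp_meanlog, cls$ipsp_sdlog), floor_mv)
  }
  mb <- cls$membrane
  j <- function(v) v * exp(rnorm(1, 0, mb$jitter))
  E_L <- rnorm(1, cfg$resting$mean, cfg$resting$sd)
  if (resp_class == "suprathreshold") epsp <- (-42 - E_L) + 5
  data.frame(
    cell_class = cls_name, response_class = resp_class,
    epsp_amp = epsp, ipsp_amp = ipsp,
    ipsp_fast_amp = ipsp * cls$ipsp_fast_frac,
    ipsp_slow_amp = ipsp * (1 - cls$ipsp_fast_frac),
    ei_ratio = if (epsp + ipsp > 0) epsp / (epsp + ipsp) else NA_real_,
    epsp_latency = max(rnorm(1, cfg$latency$epsp_mean, cfg$latency$epsp_sd),
                       1),
    train_growth = runif(1, cls$train_growth[1], cls$train_growth[2]),
    ml_distance_um = runif(1, cfg$position$ml_range[1],
                           cfg$position$ml_range[2]),
    dv_depth_mm = runif(1, cfg$position$dv_range[1], cfg$position$dv_range[2]),
    E_L = E_L, C = j(mb$C), g_L = j(mb$g_L),
    a = if (mb$a > 0) j(mb$a) else 0, tau_w = j(mb$tau_w),
    series_resistance_MOhm = runif(1, cfg$series_res_range[1],
                                   cfg$series_res_range[2]),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministic given `(config, seed)`. Class counts equal the configured
#' mixtures exactly (allocation by largest remainder; randomness only within
#' class). Ground truth records every drawn parameter.
#'
#' @param config a [default_cohort_config()]-style list.
#' @param seed integer seed.
#' @param simulate_sweeps also simulate `n_sweeps` single-pulse opto sweeps
#'   per cell (memory scales with cohort size; disable for parameter-only
#'   studies).
#' @return list with `cohort` (a [cohort()]), `ground_truth` (one row per
#'   cell) and `config`.
#' @export
generate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            simulate_sweeps = TRUE) {
  set.seed(seed %% .Machine$integer.max)
  gt <- list()
  for (cls_name in names(config$classes)) {
    cls <- config$classes[[cls_name]]
    cnt <- mixture_counts(cls$mixture, cls$n)
    classes <- sample(rep(names(cnt), cnt))
    for (rc in classes)
      gt[[length(gt) + 1L]] <- draw_cell(cls_name, cls, rc, config)
  }
  gt <- do.call(rbind, gt)
  gt$cell_id <- sprintf("c%03d", seq_len(nrow(gt)))
  gt <- gt[, c("cell_id", setdiff(names(gt), "cell_id"))]
  cells <- cell_record(gt$cell_id, gt$cell_class, gt$ml_distance_um,
                       gt$dv_depth_mm, resting_vm_mV = gt$E_L,
                       series_resistance_MOhm = gt$series_resistance_MOhm)
  sweeps <- list()
  if (simulate_sweeps) {
    for (i in seq_len(nrow(gt))) {
      sweeps[[gt$cell_id[i]]] <- simulate_cell_sweeps(
        gt[i, ], config, protocol_kind = "opto_pulse",
        seed = cell_seed(seed, i))
    }
  }
  list(cohort = cohort(cells, sweeps), ground_truth = gt, config = config)
}

cell_seed <- function(seed, i) (seed + 104729 * i) %% 2147483647

#' Membrane parameters implied by a ground-truth row
#'
#' @param gt_row one row of the ground-truth table.
#' @param config the cohort configuration (noise settings).
#' @return a [membrane_params()].
#' @export
cell_membrane <- function(gt_row, config) {
  membrane_params(C = gt_row$C, g_L = gt_row$g_L, E_L = gt_row$E_L,
                  a = gt_row$a, tau_w = gt_row$tau_w,
                  noise_sd = config$noise_sd, noise_tau = config$noise_tau)
}

#' Synapse parameters implied by a ground-truth row
#'
#' @param gt_row one row of the ground-truth table.
#' @param config the cohort configuration.
#' @param condition pharmacological condition: `"baseline"`, `"gabazine"`
#'   (fast IPSP removed), `"cgp"` (slow IPSP removed), `"gabazine_cgp"`,
#'   `"nbqx_apv"`, `"ttx"` (all removed), `"ttx_4ap"` (EPSP only).
#' @param n_pulses train length for per-pulse scaling. During trains the
#'   excitatory component is flat, the fast (GABA_A-like) inhibitory
#'   component scales linearly from 1 to the cell's `train_growth`
#'   (progressive recruitment of feedforward inhibition), and the slow
#'   (GABA_B-like) component saturates: after the first pulse its increments
#'   are damped by `1 - exp(-interval/decay)` so the accumulated slow
#'   conductance-equivalent holds near the single-pulse amplitude instead of
#'   summating without bound.
#' @param frequency_hz train frequency (sets the inter-pulse interval used by
#'   the saturation rule).
#' @return a [synapse_params()].
#' @export
cell_synapse <- function(gt_row, config, condition = "baseline",
                         n_pulses = 1L, frequency_hz = 10) {
  e <- gt_row$epsp_amp
  i_f <- gt_row$ipsp_fast_amp
  i_s <- gt_row$ipsp_slow_amp
  switch(condition,
         baseline = NULL,
         gabazine = { i_f <- 0 },
         cgp = { i_s <- 0 },
         gabazine_cgp = { i_f <- 0; i_s <- 0 },
         nbqx_apv = ,
         ttx = { e <- 0; i_f <- 0; i_s <- 0 },
         ttx_4ap = { i_f <- 0; i_s <- 0 },
         stop("unknown condition: ", condition))
  kin <- config$kinetics
  lat <- gt_row$epsp_latency
  scaling <- NULL
  if (n_pulses > 1L) {
    ramp <- seq(1, gt_row$train_growth, length.out = n_pulses)
    damp <- 1 - exp(-(1000 / frequency_hz) / kin$ipsp_slow[["decay"]])
    scaling <- list(epsp_fast = rep(1, n_pulses), ipsp_fast = ramp,
                    ipsp_slow = c(1, rep(damp, n_pulses - 1L)))
  }
  synapse_params(
    epsp_fast = c(amp = e, rise = kin$epsp[["rise"]],
                  decay = kin$epsp[["decay"]], latency = lat),
    ipsp_fast = c(amp = -i_f, rise = kin$ipsp_fast[["rise"]],
                  decay = kin$ipsp_fast[["decay"]],
                  latency = lat + config$latency$ipsp_fast_delay),
    ipsp_slow = c(amp = -i_s, rise = kin$ipsp_slow[["rise"]],
                  decay = kin$ipsp_slow[["decay"]],
                  latency = lat + config$latency$ipsp_slow_delay),
    train_scaling = scaling)
}

#' Simulate one cell's sweeps for a protocol
#'
#' @param gt_row one ground-truth row.
#' @param config cohort configuration.
#' @param protocol_kind `"opto_pulse"`, `"opto_train"`, `"current_step"`,
#'   `"current_ramp"` or `"zap"`.
#' @param condition pharmacological condition (opto protocols).
#' @param seed integer seed.
#' @param step_pa step amplitude for `current_step`.
#' @return list of [sweep()] objects.
#' @export
simulate_cell_sweeps <- function(gt_row, config, protocol_kind = "opto_pulse",
                                 condition = "baseline", seed = 1L,
                                 step_pa = -80) {
  mb <- cell_membrane(gt_row, config)
  id <- gt_row$cell_id
  if (protocol_kind %in% c("opto_pulse", "opto_train")) {
    prot <- if (protocol_kind == "opto_pulse")
      stimulus_protocol("opto_pulse", onset_ms = config$opto$onset_ms,
                        pulse_ms = config$opto$pulse_ms)
    else stimulus_protocol("opto_train", onset_ms = config$train$onset_ms,
                           frequency_hz = config$train$frequency_hz,
                           n_pulses = config$train$n_pulses,
                           pulse_ms = config$train$pulse_ms)
    np <- if (protocol_kind == "opto_train") config$train$n_pulses else 1L
    syn <- cell_synapse(gt_row, config, condition, n_pulses = np,
                        frequency_hz = config$train$frequency_hz)
    return(simulate_evoked(mb, syn, prot, n_sweeps = config$n_sweeps,
                           seed = seed, cell_id = id,
                           condition = condition)$sweeps)
  }
  prot <- switch(protocol_kind,
    current_step = stimulus_protocol("current_step", onset_ms = 500,
                                     amplitude_pa = step_pa,
                                     duration_ms = 3000),
    current_ramp = stimulus_protocol("current_ramp", onset_ms = 500,
                                     slope_pa_per_s = 50, duration_ms = 3000),
    zap = {
      zmax <- max(analytic_impedance(mb, seq(0.5, 20, by = 0.1)))
      stimulus_protocol("zap", onset_ms = 0, min_hz = 0.5, max_hz = 20,
                        duration_ms = 20000,
                        amplitude_pa = 4000 / zmax)  # ~4 mV peak excursion
    },
    stop("unsupported protocol kind: ", protocol_kind))
  dur <- switch(protocol_kind, current_step = 4000, current_ramp = 4000,
                zap = 20000)
  list(simulate_membrane(mb, prot, dur, seed = seed, cell_id = id,
                         condition = condition))
}
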