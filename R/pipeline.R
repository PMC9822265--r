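# Orchestration: simulate -> extract -> quantify -> test, as a pure function
# of (config, seed). The default configuration mirrors the study design:
# layer-2 cohort mixtures, 10 Hz trains, layer-1-enriched puncta fields and
# laminar intensity profiles, and the statistical battery (Friedman with
# Kendall's W and pairwise Wilcoxon post-hocs, Kruskal-Wallis with eta
# squared, Mann-Whitney, Kolmogorov-Smirnov, and position regressions).

#' Default experiment configuration
#'
#' @param noise_sd recording noise, mV.
#' @return nested list accepted by [run_experiment()].
#' @export
default_run_config <- function(noise_sd = 0.2) {
  list(
    cohort = default_cohort_config(noise_sd = noise_sd),
    intrinsic_n = 6,   # cells per class receiving the full intrinsic battery
    train_n = 10,      # cells per class receiving 10 Hz trains
    anatomy = list(
      n_slices = 11,
      layer_widths_um = c(L1 = 100, L2 = 150, L3 = 250, L5a = 150,
                          L5b = 200),
      ml_extent_um = 900, z_depth_um = 400,
      rates_mm3 = c(L1 = 4790, L2 = 1500, L3 = 500, L5a = 600, L5b = 1400),
      ml_gradient = c(1, 0.95, 0.85, 0.7, 0.6, 0.55)),
    intensity = list(n_slices = 6, mec_mean = 50, dg_mean = 50, sd = 12,
                     peak_pos_um = 50, width_um = 60, baseline = 40,
                     amplitude = 120, profile_noise_sd = 6))
}

#' Read an experiment configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()] values (shallow,
#' per top-level section).
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  user <- yaml::read_yaml(path)
  merge_cfg(default_run_config(), user)
}

# recursive override of defaults; YAML lists standing in for atomic vectors
# are collapsed back to vectors
merge_cfg <- function(base, user) {
  if (is.atomic(base) && is.list(user)) return(unlist(user))
  if (!is.list(base) || !is.list(user)) return(user)
  for (nm in names(user)) base[[nm]] <- merge_cfg(base[[nm]], user[[nm]])
  base
}

config_hash <- function(config) {
  txt <- yaml::as.yaml(config)
  codes <- utf8ToInt(txt)
  sprintf("%08x", Reduce(function(h, c) (h * 31 + c) %% 2147483647,
                         codes, 17))
}

stats_row <- function(analysis, res) {
  data.frame(analysis = analysis, test = res$test,
             statistic = res$statistic,
             df = if (is.null(res$df)) NA_character_ else
               paste(res$df, collapse = ","),
             p_value = res$p_value,
             effect_size = if (is.null(res$effect_size)) NA_real_ else
               res$effect_size,
             method = res$method, stringsAsFactors = FALSE)
}

regression_row <- function(analysis, fit) {
  data.frame(analysis = analysis, test = "OLS F-test",
             statistic = fit$f_statistic,
             df = paste(fit$df, collapse = ","), p_value = fit$p_value,
             effect_size = fit$r_squared, method = "exact",
             stringsAsFactors = FALSE)
}

# evoked measurement for every cell in the ground-truth table
measure_cohort_evoked <- function(gt, cfg, seed) {
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    sw <- simulate_cell_sweeps(gt[i, ], cfg, "opto_pulse",
                               seed = cell_seed(seed, i))
    m <- measure_evoked(sw)
    m$cell_class <- gt$cell_class[i]
    m$ml_distance_um <- gt$ml_distance_um[i]
    m$dv_depth_mm <- gt$dv_depth_mm[i]
    m
  })
  do.call(rbind, rows)
}

measure_cohort_trains <- function(gt, cfg, seed, per_class_n) {
  idx <- unlist(lapply(split(seq_len(nrow(gt)), gt$cell_class), function(ii) {
    ii <- ii[gt$response_class[ii] == "biphasic"]
    head(ii, per_class_n)
  }))
  rows <- lapply(idx, function(i) {
    sw <- simulate_cell_sweeps(gt[i, ], cfg, "opto_train",
                               seed = cell_seed(seed, 100000L + i))
    m <- measure_train(sw)
    m$cell_class <- gt$cell_class[i]
    m
  })
  do.call(rbind, rows)
}

measure_cohort_intrinsic <- function(gt, cfg, seed, per_class_n) {
  idx <- unlist(lapply(split(seq_len(nrow(gt)), gt$cell_class),
                       function(ii) head(ii, per_class_n)))
  rows <- lapply(idx, function(i) {
    st <- simulate_cell_sweeps(gt[i, ], cfg, "current_step",
                               seed = cell_seed(seed, 200000L + i))[[1]]
    rp <- simulate_cell_sweeps(gt[i, ], cfg, "current_ramp",
                               seed = cell_seed(seed, 300000L + i))[[1]]
    zp <- simulate_cell_sweeps(gt[i, ], cfg, "zap",
                               seed = cell_seed(seed, 400000L + i))[[1]]
    pr <- intrinsic_profile(st, rp, zp)
    pr$cell_class <- gt$cell_class[i]
    mb <- cell_membrane(gt[i, ], cfg)
    pr$rin_true <- 1000 / (gt$g_L[i] + gt$a[i])
    ar <- analytic_resonance(mb)
    pr$resonance_true <- ar$freq_hz
    pr$resonant_true <- ar$resonant
    pr
  })
  do.call(rbind, rows)
}

anatomy_analysis <- function(an, seed) {
  geom <- slice_geometry(an$layer_widths_um, an$ml_extent_um, an$z_depth_um)
  layer_mat <- ml_mat <- NULL
  for (s in seq_len(an$n_slices)) {
    pf <- generate_puncta(geom, an$rates_mm3, an$ml_gradient,
                          seed = cell_seed(seed, 500000L + s))
    ld <- layer_density_profile(pf$puncta, geom)
    mp <- mediolateral_profile(pf$puncta, geom)
    layer_mat <- rbind(layer_mat, setNames(ld$density_mm3, ld$layer))
    ml_mat <- rbind(ml_mat, setNames(mp$density_mm3,
                                     paste0("ml", mp$bin_start_um)))
  }
  list(layer_mat = layer_mat, ml_mat = ml_mat,
       layer_friedman = friedman_rank_test(layer_mat),
       layer_pairwise = pairwise_signed_rank(layer_mat),
       ml_friedman = friedman_rank_test(ml_mat))
}

#' Run a full simulated experiment
#'
#' Generates a cohort, measures evoked responses for every cell and train and
#' intrinsic responses for per-class subsets, quantifies synthetic anatomy
#' (puncta and intensity), runs the statistical battery, and summarises
#' recovery of ground truth. Deterministic given `(config, seed)`.
#'
#' @param config a [default_run_config()]-style list.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, all tables are written as
#'   tab-delimited files together with a `run_log.txt`.
#' @return list with `evoked`, `train`, `intrinsic`, `anatomy_layers`,
#'   `anatomy_ml`, `stats` (long table), `recovery`, `proportions`, `log`.
#' @export
run_experiment <- function(config = default_run_config(), seed = 1L,
                           out_dir = NULL) {
  gen <- generate_cohort(config$cohort, seed = seed, simulate_sweeps = FALSE)
  gt <- gen$ground_truth
  evoked <- measure_cohort_evoked(gt, config$cohort, seed)
  train <- measure_cohort_trains(gt, config$cohort, seed, config$train_n)
  intrinsic <- measure_cohort_intrinsic(gt, config$cohort, seed,
                                        config$intrinsic_n)
  an <- anatomy_analysis(config$anatomy, seed)

  # intensity comparison between target structures (similar by construction)
  set.seed(cell_seed(seed, 600000L))
  ints <- config$intensity
  mec_int <- rnorm(ints$n_slices, ints$mec_mean, ints$sd)
  dg_int <- rnorm(ints$n_slices, ints$dg_mean, ints$sd)
  prof <- generate_intensity_profile(ints$peak_pos_um, ints$width_um,
                                     ints$baseline, ints$amplitude,
                                     ints$profile_noise_sd,
                                     seed = cell_seed(seed, 600001L))
  prof_norm <- normalize_profile(prof$profile$raw)

  stats <- list()
  stats[[1]] <- stats_row("puncta density ~ layer", an$layer_friedman)
  stats[[2]] <- stats_row("puncta density ~ ml bin", an$ml_friedman)
  stats[[3]] <- stats_row("intensity MEC vs DG",
                          rank_sum_test(mec_int, dg_int))
  by_class <- split(evoked$epsp_amp[evoked$epsp_amp > 0],
                    evoked$cell_class[evoked$epsp_amp > 0])
  stats[[4]] <- stats_row("EPSP amplitude ~ cell class",
                          kruskal_wallis_test(by_class))
  bi <- evoked[evoked$classification == "biphasic", ]
  sc <- bi[bi$cell_class == "L2_SC", ]
  pc <- bi[bi$cell_class == "L2_PC", ]
  stats[[5]] <- stats_row("E-I ratio SC vs PC",
                          rank_sum_test(pc$ei_ratio, sc$ei_ratio))
  stats[[6]] <- regression_row("E-I ~ ml position (SC)",
                               linear_regression_f(sc$ml_distance_um,
                                                   sc$ei_ratio))
  stats[[7]] <- regression_row("E-I ~ dv position (SC)",
                               linear_regression_f(sc$dv_depth_mm,
                                                   sc$ei_ratio))
  stats[[8]] <- regression_row("E-I ~ ml position (PC)",
                               linear_regression_f(pc$ml_distance_um,
                                                   pc$ei_ratio))
  stats[[9]] <- regression_row("E-I ~ dv position (PC)",
                               linear_regression_f(pc$dv_depth_mm,
                                                   pc$ei_ratio))
  # train: pulse 1 vs 10 (paired) and pulse-10 E-I dispersion SC vs PC
  p1 <- train[train$pulse == 1, ]
  p10 <- train[train$pulse == 10, ]
  sc1 <- p1$cell_id[p1$cell_class == "L2_SC"]
  if (length(sc1) >= 2) {
    i1 <- p1$ipsp_amp[match(sc1, p1$cell_id)]
    i10 <- p10$ipsp_amp[match(sc1, p10$cell_id)]
    stats[[length(stats) + 1L]] <-
      stats_row("SC IPSP pulse 1 vs 10", signed_rank_test(i1, i10))
  }
  ei10_sc <- p10$ei_ratio[p10$cell_class == "L2_SC"]
  ei10_pc <- p10$ei_ratio[p10$cell_class == "L2_PC"]
  if (length(ei10_sc) >= 2 && length(ei10_pc) >= 2)
    stats[[length(stats) + 1L]] <-
      stats_row("pulse-10 E-I SC vs PC", ks2_test(ei10_sc, ei10_pc))
  stats <- do.call(rbind, stats)

  # recovery of ground truth
  m <- merge(evoked, gt[, c("cell_id", "response_class", "epsp_amp",
                            "ipsp_amp", "ei_ratio")],
             by = "cell_id", suffixes = c("", "_true"))
  cls_acc <- mean(m$classification == m$response_class)
  amp_err <- m$epsp_amp - m$epsp_amp_true
  recovery <- data.frame(
    metric = c("classification_accuracy", "epsp_bias_mV", "epsp_rmse_mV",
               "ipsp_bias_mV", "ipsp_rmse_mV", "ei_rmse",
               "rin_rmse_pct", "resonance_rmse_hz"),
    value = c(cls_acc, mean(amp_err), sqrt(mean(amp_err^2)),
              mean(m$ipsp_amp - m$ipsp_amp_true),
              sqrt(mean((m$ipsp_amp - m$ipsp_amp_true)^2)),
              sqrt(mean((m$ei_ratio - m$ei_ratio_true)^2, na.rm = TRUE)),
              sqrt(mean((100 * (intrinsic$input_resistance -
                                  intrinsic$rin_true) /
                           intrinsic$rin_true)^2)),
              sqrt(mean((intrinsic$resonance_freq -
                           intrinsic$resonance_true)^2,
                        na.rm = TRUE))))

  proportions <- do.call(rbind, lapply(split(evoked, evoked$cell_class),
    function(d) {
      tb <- tabulate_responses(d$classification)
      tb$cell_class <- d$cell_class[1]
      tb
    }))

  log <- data.frame(
    key = c("seed", "config_hash", "package_version", "n_cells", "timestamp"),
    value = c(seed, config_hash(config), as.character(
      utils::packageVersion("fancircuit")), nrow(gt),
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    stringsAsFactors = FALSE)

  report <- list(evoked = evoked, train = train, intrinsic = intrinsic,
                 anatomy_layers = an$layer_mat, anatomy_ml = an$ml_mat,
                 anatomy_layer_pairwise = an$layer_pairwise,
                 intensity_profile = data.frame(
                   position_um = prof$profile$position_um,
                   raw = prof$profile$raw, normalized = prof_norm),
                 stats = stats, recovery = recovery,
                 proportions = proportions, ground_truth = gt, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("evoked", "train", "intrinsic",
                 "anatomy_layer_pairwise", "intensity_profile", "stats",
                 "recovery", "proportions", "ground_truth", "log"))
      write.table(report[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report$anatomy_layers),
                file.path(out_dir, "anatomy_layers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report$anatomy_ml),
                file.path(out_dir, "anatomy_ml.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report
}
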