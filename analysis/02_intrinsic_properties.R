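#!/usr/bin/env Rscript
# Intrinsic membrane properties of a per-class subset of the cohort.
#
# Each selected cell receives the full intrinsic battery: a -80 pA / 3 s
# hyperpolarizing step (input resistance, membrane time constant, sag), a
# 50 pA/s depolarizing ramp (rheobase and action-potential features), and a
# 0.5-20 Hz / 20 s chirp (impedance spectrum and resonance frequency).
# Measured values are scored against the generator's closed-form ground
# truth.

library(fancircuit)

SEED <- 1L
PER_CLASS <- 8L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_cohort_config(noise_sd = 0.2)
gt <- generate_cohort(cfg, seed = SEED, simulate_sweeps = FALSE)$ground_truth
idx <- unlist(lapply(split(seq_len(nrow(gt)), gt$cell_class),
                     function(ii) head(ii, PER_CLASS)))

rows <- lapply(idx, function(i) {
  sub_seed <- function(k) (SEED + 104729 * (k + i)) %% 2147483647
  st <- simulate_cell_sweeps(gt[i, ], cfg, "current_step",
                             seed = sub_seed(200000L))[[1]]
  rp <- simulate_cell_sweeps(gt[i, ], cfg, "current_ramp",
                             seed = sub_seed(300000L))[[1]]
  zp <- simulate_cell_sweeps(gt[i, ], cfg, "zap",
                             seed = sub_seed(400000L))[[1]]
  pr <- intrinsic_profile(st, rp, zp)
  pr$cell_class <- gt$cell_class[i]
  pr$rin_true <- 1000 / (gt$g_L[i] + gt$a[i])
  ar <- analytic_resonance(cell_membrane(gt[i, ], cfg))
  pr$resonance_true <- ar$freq_hz
  pr
})
intrinsic <- do.call(rbind, rows)
write.table(intrinsic, file.path(out, "intrinsic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-class medians:\n")
print(do.call(rbind, lapply(split(intrinsic, intrinsic$cell_class),
  function(d) c(Rin_MOhm = median(d$input_resistance),
                tau_ms = median(d$tau_m),
                sag = median(d$sag_ratio),
                rheobase_pA = median(d$rheobase, na.rm = TRUE),
                res_Hz = median(d$resonance_freq)))))
cat(sprintf("\nRin recovery: max |error| %.2f%% of truth\n",
            100 * max(abs(intrinsic$input_resistance - intrinsic$rin_true) /
                        intrinsic$rin_true)))
cat(sprintf("resonance recovery: max |error| %.2f Hz (resonant cells)\n",
            max(abs(intrinsic$resonance_freq[intrinsic$resonant] -
                      intrinsic$resonance_true[intrinsic$resonant]))))
cat("wrote", file.path(out, "intrinsic.tsv"), "\n")
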