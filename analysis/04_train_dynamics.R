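#!/usr/bin/env Rscript
# 10 Hz train dynamics for biphasic cells: per-pulse EPSP/IPSP amplitudes and
# E-I ratios against the 990 ms pre-train baseline, pulse-1 vs pulse-10
# paired Wilcoxon contrasts, and the Kolmogorov-Smirnov comparison of
# pulse-10 E-I dispersion between stellate and pyramidal cells.

library(fancircuit)

SEED <- 1L
PER_CLASS <- 10L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_cohort_config(noise_sd = 0.2)
gt <- generate_cohort(cfg, seed = SEED, simulate_sweeps = FALSE)$ground_truth
idx <- unlist(lapply(split(seq_len(nrow(gt)), gt$cell_class), function(ii)
  head(ii[gt$response_class[ii] == "biphasic"], PER_CLASS)))

train <- do.call(rbind, lapply(idx, function(i) {
  sw <- simulate_cell_sweeps(gt[i, ], cfg, "opto_train",
                             seed = (SEED + 104729 * (100000L + i)) %%
                               2147483647)
  m <- measure_train(sw)
  m$cell_class <- gt$cell_class[i]
  m
}))
write.table(train, file.path(out, "train.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

p1 <- train[train$pulse == 1, ]
p10 <- train[train$pulse == 10, ]
for (cl in unique(train$cell_class)) {
  ids <- p1$cell_id[p1$cell_class == cl]
  a1 <- p1[match(ids, p1$cell_id), ]
  a10 <- p10[match(ids, p10$cell_id), ]
  cat("\n", cl, " (n = ", length(ids), "):\n", sep = "")
  for (ft in c("epsp_amp", "ipsp_amp", "ei_ratio")) {
    d1 <- a1[[ft]]; d10 <- a10[[ft]]
    keep <- stats::complete.cases(d1, d10)
    res <- tryCatch(signed_rank_test(d1[keep], d10[keep]),
                    error = function(e) NULL)
    cat(sprintf("  %s: pulse1 %.3f -> pulse10 %.3f, V = %s, p = %s\n",
                ft, mean(d1, na.rm = TRUE), mean(d10, na.rm = TRUE),
                if (is.null(res)) "-" else format(res$statistic),
                if (is.null(res)) "-" else format(res$p_value, digits = 3)))
  }
}

ei_sc <- p10$ei_ratio[p10$cell_class == "L2_SC"]
ei_pc <- p10$ei_ratio[p10$cell_class == "L2_PC"]
ks <- ks2_test(ei_sc, ei_pc)
cat(sprintf("\npulse-10 E-I, SC vs PC: D = %.3f, p = %.3g (SC IQR %.3f, PC IQR %.3f)\n",
            ks$statistic, ks$p_value, IQR(ei_sc), IQR(ei_pc)))
cat("wrote", file.path(out, "train.tsv"), "\n")
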