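#!/usr/bin/env Rscript
# Threshold analysis: sweep the occult-metastasis rate and find the largest
# value at which SLNB-guided neck dissection stays cost-effective at the
# one-time GDP-per-capita willingness-to-pay threshold.

suppressPackageStartupMessages(library(slnbcea))
dir.create("results", showWarnings = FALSE)

params <- table1_defaults()
grid <- seq(0.05, 0.95, by = 0.01)

ts <- threshold_sweep(params, grid = grid, comparison = c("I", "II"))
utils::write.csv(ts$grid, "results/threshold_occult_rate.csv",
                 row.names = FALSE)

cat(sprintf("Occult-metastasis threshold (SLNB vs END alone, WTP %s):\n",
            format(params$config$wtp_threshold, big.mark = ",")))
cat(sprintf("  breakpoint %.2f (grid resolution %.2f)\n",
            ts$breakpoint, ts$resolution))

ts3 <- threshold_sweep(params, grid = grid, comparison = c("I", "III"))
cat(sprintf("  versus END+FS instead: breakpoint %.2f\n", ts3$breakpoint))

write_run_manifest("results/threshold_manifest.json", params, seed = NA,
                   outputs = "results/threshold_occult_rate.csv",
                   extra = list(breakpoint_vs_II = ts$breakpoint,
                                breakpoint_vs_III = ts3$breakpoint,
                                grid_resolution = ts$resolution))
cat("wrote results/threshold_occult_rate.csv\n")
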