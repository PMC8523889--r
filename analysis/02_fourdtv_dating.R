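#!/usr/bin/env Rscript
# Corrected 4dTv per paralog pair, the binned distribution and its modal
# peak, and the conversion of that peak to an absolute WGD age against the
# 3R calibration (320 Mya / peak 0.65-0.75).

library(fourdtv)

seed <- 42
dir.create("results", showWarnings = FALSE)

report <- run_wgd_pipeline(
  wgd_d = 0.04, n_pairs = 1000, n_background = 300,
  background_d_range = c(0.1, 0.6), n_codons = 500,
  model = hky_model(kappa = 2), seed = seed,
  bin_width = 0.01, T_3R = 320, v_3R = c(0.65, 0.75)
)

message(sprintf("pairs: %d ok, %d saturated, %d without 4d sites",
                report$n_ok, report$n_saturated, report$n_no_sites))
message(sprintf("modal peak (bin lower edge): %.2f, height %d",
                report$peak, report$peak_height))
message(sprintf("WGD age: %.1f Mya (range %.1f-%.1f under the 0.65-0.75 calibration)",
                report$T_point, report$T_range[1], report$T_range[2]))

write_pair_stats(utils::head(report$stats, 100), "results/pair_stats_head.tsv")
write_histogram_tsv(report$histogram, "results/fourdtv_histogram.tsv")
write_dating_report(report, "results/wgd_dating.json")
message("wrote results/fourdtv_histogram.tsv, results/wgd_dating.json")
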