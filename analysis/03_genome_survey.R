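#!/usr/bin/env Rscript
# Genome-survey arithmetic: the published 17-mer worked example, coverage
# and completeness percentages, gene accounting, and a recovery check on a
# fully simulated spectrum.

library(fourdtv)

dir.create("results", showWarnings = FALSE)

# published worked example: K_num and K_depth as printed
K_num <- 40525178512
K_depth <- 23
size <- genome_size_estimate(K_num, K_depth)
message(sprintf("printed K_num / K_depth: %.0f / %d -> %.0f bp (%.1f Gb)",
                K_num, K_depth, size, fourdtv:::round_half_up(size / 1e9, 1)))

cov <- percent_of(1.7, 1.8)
busco <- percent_of(3536, 3640)
acc <- gene_accounting(32150, 7827)
message(sprintf("assembly coverage of the estimate: %.1f%%", cov))
message(sprintf("complete BUSCOs: %.1f%%", busco))
message(sprintf("gene accounting: %d clustered + %d unclustered = %d",
                acc$clustered, acc$unclustered, acc$total))

# recovery on the simulated spectrum written by 01_simulate.R
hist <- read_kmer_histogram("results/sim/kmer_histogram.tsv")
sv <- survey_genome_size(hist)
message(sprintf("simulated 1 Mb spectrum: K_depth %d, estimate %.0f bp (%+.2f%%)",
                sv$K_depth, sv$size_bp, 100 * (sv$size_bp - 1e6) / 1e6))

jsonlite::write_json(
  list(worked_example = list(K_num = K_num, K_depth = K_depth,
                             size_bp = size,
                             size_gb = fourdtv:::round_half_up(size / 1e9, 1)),
       assembly_coverage_pct = cov,
       busco_complete_pct = busco,
       gene_accounting = acc,
       simulated_recovery = sv),
  "results/genome_survey.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
message("wrote results/genome_survey.json")
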