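#!/usr/bin/env Rscript
# Homolog-hit selection and collinear-block chaining: threshold filtering
# (aligned ratio >= 0.5, identity >= 0.5), reciprocal-overlap redundancy
# removal, and gap-bounded monotonic chaining of the simulated anchors.

library(fourdtv)

seed <- 42
set.seed(seed)
dir.create("results", showWarnings = FALSE)

# a synthetic TBLASTn-like hit table: half good hits, half failing a filter
n <- 60
starts <- sample.int(5000, n)
hits <- data.frame(
  query_id = sprintf("q%02d", sample.int(15, n, replace = TRUE)),
  target_id = sprintf("hit%03d", seq_len(n)),
  target_scaffold = sample(sprintf("scf%d", 1:4), n, replace = TRUE),
  target_start = starts,
  target_end = starts + sample(200:900, n, replace = TRUE),
  aligned_ratio = round(stats::runif(n, 0.2, 1), 2),
  identity = round(stats::runif(n, 0.2, 1), 2),
  score = sample.int(500, n)
)
kept <- filter_hits(hits)
nr <- remove_redundant(kept)
message(sprintf("hits: %d raw -> %d after thresholds -> %d after redundancy removal",
                nrow(hits), nrow(kept), nrow(nr)))
utils::write.table(nr, "results/filtered_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

anchors <- read_anchors_tsv("results/sim/anchors.tsv")
blocks <- collinear_blocks(anchors, min_anchors = 3, max_gap = 15)
message(sprintf("anchors: %d -> %d collinear blocks covering %d anchors",
                nrow(anchors),
                if (nrow(blocks)) max(blocks$block_id) else 0, nrow(blocks)))
write_blocks_tsv(blocks, "results/collinear_blocks.tsv")
message("wrote results/filtered_hits.tsv, results/collinear_blocks.tsv")
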