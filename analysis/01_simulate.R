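#!/usr/bin/env Rscript
# Generate the synthetic datasets every later stage consumes: a paralog pair
# set with a WGD burst, a 17-mer depth spectrum with an error component, and
# a gene-order anchor set with planted collinear blocks. Everything is
# seeded, so downstream drivers regenerate the larger objects instead of
# shipping them around.

library(fourdtv)

seed <- 42
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

message("paralogome: 1,000 WGD pairs at corrected 4dTv 0.04 + 300 background")
paralogome <- simulate_paralogome(
  n_wgd = 1000, n_background = 300, wgd_d = 0.04,
  background_d_range = c(0.1, 0.6), n_codons = 500,
  model = hky_model(kappa = 2), seed = seed
)
manifest <- write_pair_fastas(paralogome$alignments[1:3],
                              "results/sim/example_pairs")
message("  wrote ", nrow(manifest), " example pair FASTAs (full set is ",
        length(paralogome$alignments), " pairs, regenerated by seed)")

message("17-mer spectrum: 1 Mb genome at 30x with 300k error k-mers")
hist <- simulate_kmer_histogram(1e6, 30, k = 17,
                                error_kmer_count = 3e5, seed = seed)
writeLines(
  c(sprintf("# simulate_kmer_histogram genome_size=1e6 mean_depth=30 error_kmer_count=3e5 seed=%d", seed),
    sprintf("%d\t%d", hist$rows$depth, hist$rows$count)),
  "results/sim/kmer_histogram.tsv"
)

message("anchors: 4 planted blocks of 8 plus 40 noise anchors")
anch <- simulate_anchors(4, 8, 40, genome_length = 300, seed = seed)
utils::write.table(anch$anchors, "results/sim/anchors.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("done; outputs under results/sim/")
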