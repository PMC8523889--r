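test_that("HKY transition matrix matches numerical matrix exponentiation", {
  for (kappa in c(1, 2, 5)) {
    m <- hky_model(kappa = kappa, pi = c(A = 0.35, C = 0.15, G = 0.3, T = 0.2))
    R <- fourdtv:::hky_rate_matrix(m)
    for (t in c(0.05, 0.1, 0.7)) {
      P <- hky_transition_matrix(m, t)
      P_ref <- as.matrix(Matrix::expm(Matrix::Matrix(R * t)))
      expect_lt(max(abs(P - P_ref)), 1e-10)
    }
  }
})

test_that("HKY transition matrix is stochastic, stationary, identity at 0", {
  m <- hky_model(kappa = 2, pi = c(A = 0.4, C = 0.1, G = 0.2, T = 0.3))
  expect_equal(unname(hky_transition_matrix(m, 0)), diag(4), tolerance = 1e-12)
  for (t in c(0.01, 0.2, 1, 5)) {
    P <- hky_transition_matrix(m, t)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_equal(as.numeric(m$pi %*% P), unname(m$pi), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # equal frequencies, long branch: every entry tends to 1/4
  expect_equal(max(abs(hky_transition_matrix(hky_model(), 100) - 0.25)), 0,
               tolerance = 1e-10)
})

test_that("simulators are deterministic under a fixed seed", {
  a1 <- simulate_pair_set(3, 40, 0.1, seed = 42)
  a2 <- simulate_pair_set(3, 40, 0.1, seed = 42)
  a3 <- simulate_pair_set(3, 40, 0.1, seed = 43)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  h1 <- simulate_kmer_histogram(1e4, 30, seed = 1)
  h2 <- simulate_kmer_histogram(1e4, 30, seed = 1)
  expect_identical(h1, h2)
})

test_that("pair simulation hits the target corrected 4dTv on average", {
  alns <- simulate_pair_set(300, 300, 0.1, seed = 21)
  df <- batch_4dtv(alns)
  expect_true(all(df$status == "ok"))
  d <- df$d_corrected
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.1), 3 * se)
  # zero divergence gives identical rows
  z <- simulate_pair_set(3, 30, 0, seed = 2)
  for (aln in z) expect_identical(aln$seq_a, aln$seq_b)
})

test_that("simulated third positions converge to the model frequencies", {
  pi <- c(A = 0.4, C = 0.25, G = 0.15, T = 0.2)
  alns <- simulate_pair_set(100, 200, 0.3, model = hky_model(2, pi), seed = 31)
  third <- unlist(lapply(alns, function(a) {
    ch <- strsplit(a$seq_a, "")[[1]]
    ch[seq(3, length(ch), by = 3)]
  }))
  freq <- table(factor(third, levels = names(pi))) / length(third)
  expect_equal(as.numeric(freq), unname(pi), tolerance = 0.05)
})

test_that("paralogome labels partition the set; no background is unimodal", {
  sim <- simulate_paralogome(50, 20, 0.05, n_codons = 100, seed = 12)
  expect_length(sim$alignments, 70)
  expect_equal(sum(sim$labels == "wgd"), 50)
  expect_equal(sum(sim$labels == "background"), 20)
  solo <- simulate_paralogome(80, 0, 0.04, n_codons = 200, seed = 13)
  expect_true(all(solo$labels == "wgd"))
})

test_that("simulated k-mer histograms behave like a Poisson depth spectrum", {
  h <- simulate_kmer_histogram(2e5, 30, seed = 5)
  # conservation: every genomic k-mer lands in exactly one depth row
  expect_equal(sum(h$rows$count), 2e5)
  raw_mode <- h$rows$depth[which.max(h$rows$count)]
  expect_lte(abs(raw_mode - 30), 2)
  # error component inflates only the low-depth tail
  he <- simulate_kmer_histogram(2e5, 30, error_kmer_count = 4e5, seed = 6)
  expect_gt(he$rows$count[he$rows$depth == 1],
            max(he$rows$count[he$rows$depth > 10]))
  expect_equal(kmer_peak_depth(he), 30, tolerance = 2 / 30)
})

test_that("pseudogene simulator closes the loop with the classifier", {
  refs <- replicate(40, random_cds(120))
  sim <- simulate_pseudogenes(refs, seed = 17)
  expect_length(sim$candidates, 40)
  for (i in seq_along(sim$candidates)) {
    fl <- classify_pseudogene(sim$candidates[[i]])
    if (sim$labels[i] == "intact") {
      expect_false(fl$is_pseudogene)
    } else {
      expect_true(fl$is_pseudogene)
      expect_true(switch(sim$labels[i],
                         stop = fl$premature_stop,
                         frameshift = fl$frameshift,
                         missing = fl$missing_exon))
    }
  }
  # all-zero lesion probabilities: everything intact
  none <- simulate_pseudogenes(refs[1:5],
                               lesion_probs = c(stop = 0, frameshift = 0,
                                                missing = 0),
                               seed = 18)
  expect_true(all(none$labels == "intact"))
})

test_that("anchor simulator plants recoverable blocks", {
  one <- simulate_anchors(1, 5, 0, seed = 9)
  blocks <- collinear_blocks(one$anchors)
  expect_equal(max(blocks$block_id), 1)
  expect_equal(nrow(blocks), 5)
  none <- simulate_anchors(0, 0, 10, genome_length = 1000, seed = 10)
  expect_equal(nrow(collinear_blocks(none$anchors)), 0)
})
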