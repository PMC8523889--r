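make_sites <- function(pairs) {
  data.frame(
    codon_column = seq_along(pairs) - 1L,
    base_a = vapply(pairs, `[`, character(1), 1),
    base_b = vapply(pairs, `[`, character(1), 2),
    is_transversion = vapply(pairs, function(p) {
      classify_change(p[1], p[2]) == "transversion"
    }, logical(1))
  )
}

test_that("pooled_base_freqs tallies both sequences and sums to one", {
  expect_equal(pooled_base_freqs(make_sites(list(c("A", "A")))),
               c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pooled_base_freqs(make_sites(list(c("A", "T"), c("C", "G")))),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  set.seed(11)
  sites <- make_sites(replicate(500, sample(c("A", "C", "G", "T"), 2,
                                            replace = TRUE),
                                simplify = FALSE))
  pi <- pooled_base_freqs(sites)
  tally <- table(factor(c(sites$base_a, sites$base_b),
                        levels = c("A", "C", "G", "T")))
  expect_equal(unname(pi), as.numeric(tally) / 1000)
  expect_equal(sum(pi), 1)
  expect_error(pooled_base_freqs(make_sites(list())), "no 4d sites")
})

test_that("raw_4dtv is the transversion fraction", {
  expect_equal(raw_4dtv(make_sites(list(c("A", "A"), c("C", "C")))), 0)
  expect_equal(raw_4dtv(make_sites(list(c("A", "T"), c("A", "G"),
                                        c("C", "C"), c("G", "C")))), 0.5)
})

test_that("hky_correct matches closed forms and flags saturation", {
  expect_equal(hky_correct(0, 0.5, 0.5), 0)
  expect_equal(hky_correct(0.3, 0.5, 0.5), -0.5 * log(0.4))
  expect_true(is.na(hky_correct(0.5, 0.5, 0.5)))
  expect_equal(hky_correct(0.001, 0.5, 0.5), 0.001, tolerance = 1e-5 / 0.001)
  # K80 equivalence across the admissible range, machine precision
  for (Q in seq(0, 0.49, by = 0.01)) {
    expect_equal(hky_correct(Q, 0.5, 0.5), -0.5 * log(1 - 2 * Q),
                 tolerance = 1e-15)
  }
  # monotone in Q, and d >= Q everywhere on the domain
  Qs <- seq(0, 0.44, by = 0.02)
  ds <- vapply(Qs, hky_correct, numeric(1), piR = 0.6, piY = 0.4)
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= Qs))
})

test_that("pair_4dtv composes sites, frequencies and correction", {
  # identical sequences of 100 fourfold codons
  set.seed(3)
  code <- standard_genetic_code()
  cod <- paste0(sample(code$fourfold_prefixes, 100, replace = TRUE),
                sample(c("A", "C", "G", "T"), 100, replace = TRUE))
  s <- paste(cod, collapse = "")
  st <- pair_4dtv(codon_pair_alignment(s, s))
  expect_equal(st$n4, 100)
  expect_equal(st$Q, 0)
  expect_equal(st$d_corrected, 0)
  expect_equal(st$status, "ok")
  # no fourfold columns at all
  st2 <- pair_4dtv(codon_pair_alignment("ATGAAA", "ATGAAG"))
  expect_equal(st2$status, "no_sites")
  expect_equal(st2$n4, 0L)
  # symmetric in the two rows
  aln <- random_fourfold_alignment(80)
  f <- pair_4dtv(aln)
  r <- pair_4dtv(codon_pair_alignment(aln$seq_b, aln$seq_a))
  expect_equal(f$Q, r$Q)
  expect_equal(f$d_corrected, r$d_corrected)
  # fields equal an oracle recomputation on a simulated pair
  aln3 <- simulate_pair_set(1, 200, 0.1, seed = 5)[[1]]
  st3 <- pair_4dtv(aln3)
  want <- oracle_4d_sites(aln3$seq_a, aln3$seq_b)
  expect_equal(st3$n4, nrow(want))
  expect_equal(st3$n_tv, sum(want$is_transversion))
  expect_equal(st3$Q, sum(want$is_transversion) / nrow(want))
})

test_that("expected_4dtv has the right limits and inverts cleanly", {
  m <- hky_model(kappa = 2)
  expect_equal(expected_4dtv(m, 0), 0)
  # stationary limit: transversion proportion tends to 2*piR*piY = 0.5
  P <- hky_transition_matrix(m, 50)
  expect_equal(max(abs(P - 0.25)), 0, tolerance = 1e-8)
  # strictly increasing
  ts <- seq(0, 2, by = 0.1)
  ds <- vapply(ts, expected_4dtv, numeric(1), model = m)
  expect_true(all(diff(ds) > 0))
  # round trip to 1e-9
  # the corrected distance is unbounded below saturation, so even large
  # targets are attainable; the round trip must still hold there
  for (d in c(0.01, 0.04, 0.06, 0.3, 0.8)) {
    t <- solve_branch_length(m, d)
    expect_equal(expected_4dtv(m, t), d, tolerance = 1e-9 / d)
  }
})

test_that("expected_4dtv agrees with Monte-Carlo simulation", {
  m <- hky_model(kappa = 3, pi = c(A = 0.3, C = 0.2, G = 0.3, T = 0.2))
  t <- 0.4
  d_exp <- expected_4dtv(m, t)
  P <- hky_transition_matrix(m, t)
  set.seed(99)
  n <- 1e5
  i <- sample.int(4, n, replace = TRUE, prob = m$pi)
  j <- vapply(i, function(b) sample.int(4, 1, prob = P[b, ]), integer(1))
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  Q_hat <- mean(purine[i] != purine[j])
  se <- sqrt(Q_hat * (1 - Q_hat) / n)
  piR <- m$pi[["A"]] + m$pi[["G"]]
  d_hat <- hky_correct(Q_hat, piR, 1 - piR)
  # delta-method SE on the corrected scale
  se_d <- se / (1 - Q_hat / (2 * piR * (1 - piR)))
  expect_lt(abs(d_hat - d_exp), 3 * se_d)
})

test_that("batch output round-trips through the TSV writer", {
  alns <- simulate_pair_set(5, 60, 0.1, seed = 8)
  df <- batch_4dtv(alns)
  expect_equal(nrow(df), 5)
  expect_true(all(df$status == "ok"))
  expect_true(all(df$d_corrected >= df$Q))
  path <- tempfile(fileext = ".tsv")
  write_pair_stats(df, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back$n4, df$n4)
  expect_equal(back$d_corrected, round(df$d_corrected, 6))
})
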