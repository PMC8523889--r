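test_that("classify_pseudogene flags each lesion class and only those", {
  set.seed(61)
  ref <- random_cds(200)
  # intact duplicate: no flags
  fl <- classify_pseudogene(codon_pair_alignment(ref, ref))
  expect_false(fl$is_pseudogene)
  expect_equal(fl$coverage, 1)
  # codon 50 (1-based) replaced by TGA -> premature stop at 0-based index 49
  cand <- ref
  substr(cand, 3 * 50 - 2, 3 * 50) <- "TGA"
  fl2 <- classify_pseudogene(codon_pair_alignment(ref, cand))
  expect_true(fl2$premature_stop)
  expect_equal(fl2$stop_codon_index, 49L)
  expect_false(fl2$frameshift)
  expect_false(fl2$missing_exon)
  # single-base gap (1 bp indel) -> frameshift
  cand3 <- ref
  substr(cand3, 100, 100) <- "-"
  fl3 <- classify_pseudogene(codon_pair_alignment(ref, cand3))
  expect_true(fl3$frameshift)
  expect_false(fl3$premature_stop)
  # a gap in the reference row (candidate insertion) also shifts the frame
  ref4 <- ref
  substr(ref4, 100, 100) <- "-"
  fl4 <- classify_pseudogene(codon_pair_alignment(ref4, ref))
  expect_true(fl4$frameshift)
  # 35 whole codons deleted -> missing region, frame intact
  cand5 <- ref
  substr(cand5, 3 * 20 - 2, 3 * (20 + 35 - 1)) <- strrep("-", 105)
  fl5 <- classify_pseudogene(codon_pair_alignment(ref, cand5))
  expect_true(fl5$missing_exon)
  expect_false(fl5$frameshift)
  expect_equal(fl5$missing_span, 35L)
  # reference with an internal stop is rejected
  bad <- ref
  substr(bad, 4, 6) <- "TAA"
  expect_error(classify_pseudogene(codon_pair_alignment(bad, bad)),
               "invalid reference")
})

test_that("a reference aligned to itself is never flagged", {
  set.seed(62)
  for (i in 1:15) {
    ref <- random_cds(sample(50:200, 1))
    expect_false(classify_pseudogene(codon_pair_alignment(ref, ref))$is_pseudogene)
  }
})

test_that("flag disjunction defines pseudogene status", {
  set.seed(63)
  refs <- replicate(60, random_cds(150))
  sim <- simulate_pseudogenes(refs, seed = 64)
  for (i in seq_along(sim$candidates)) {
    fl <- classify_pseudogene(sim$candidates[[i]])
    expect_equal(fl$is_pseudogene,
                 fl$premature_stop || fl$frameshift || fl$missing_exon)
  }
})

test_that("copy_number_profile counts intact and pseudogene loci", {
  cands <- data.frame(
    query_gene = c("bcl2l1", "bcl2l1", "ask1", "ask1", "ask1"),
    species = c("spA", "spA", "spA", "spA", "spB"),
    locus_id = c("l1", "l2", "l3", "l4", "l5"),
    is_pseudogene = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  prof <- copy_number_profile(cands)
  b <- prof[prof$query_gene == "bcl2l1", ]
  expect_equal(c(b$intact_count, b$pseudogene_count), c(2, 0))
  # one intact copy plus one pseudogenized copy, the ask1-like pattern
  a <- prof[prof$query_gene == "ask1" & prof$species == "spA", ]
  expect_equal(c(a$intact_count, a$pseudogene_count), c(1, 1))
  expect_equal(prof$total, prof$intact_count + prof$pseudogene_count)
  # duplicated locus rows count once
  dup <- rbind(cands, cands[1, ])
  expect_equal(copy_number_profile(dup), prof)
})

test_that("tetraploid versus diploid profiling recovers the 2x ratio", {
  set.seed(65)
  genes <- sprintf("gene%02d", 1:20)
  diploid <- data.frame(query_gene = genes, species = "diploid",
                        locus_id = paste0(genes, "_l1"),
                        is_pseudogene = FALSE)
  tetra <- rbind(
    data.frame(query_gene = genes, species = "tetraploid",
               locus_id = paste0(genes, "_l1"),
               is_pseudogene = FALSE),
    data.frame(query_gene = genes, species = "tetraploid",
               locus_id = paste0(genes, "_l2"),
               is_pseudogene = stats::runif(20) < 0.15)
  )
  prof <- copy_number_profile(rbind(diploid, tetra))
  tot <- tapply(prof$total, prof$species, mean)
  expect_equal(unname(tot[["tetraploid"]] / tot[["diploid"]]), 2.0,
               tolerance = 0.05)
})

test_that("copy matrix TSV writer formats intact/pseudo cells", {
  cands <- data.frame(query_gene = c("g1", "g1", "g2"),
                      species = c("spA", "spA", "spB"),
                      locus_id = c("l1", "l2", "l3"),
                      is_pseudogene = c(FALSE, TRUE, FALSE))
  path <- tempfile(fileext = ".tsv")
  write_copy_matrix(copy_number_profile(cands), path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(tab$spA[tab$query_gene == "g1"], "1/1")
  expect_equal(tab$spB[tab$query_gene == "g2"], "1/0")
  expect_equal(tab$spB[tab$query_gene == "g1"], "0/0")
})
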