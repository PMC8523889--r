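# Independent brute-force oracles. Deliberately naive: per-element loops and
# exhaustive enumeration, sharing no code path with the package internals.

oracle_translate <- function(codon) {
  code <- standard_genetic_code()
  unname(code$codon_to_aa[codon])
}

# per-codon-column scan; fourfold test done by translating all four codons
oracle_4d_sites <- function(seq_a, seq_b) {
  acgt <- c("A", "C", "G", "T")
  n <- nchar(seq_a) %/% 3L
  out <- list()
  for (i in seq_len(n)) {
    ca <- substr(seq_a, 3 * i - 2, 3 * i)
    cb <- substr(seq_b, 3 * i - 2, 3 * i)
    ch_a <- strsplit(ca, "")[[1]]
    ch_b <- strsplit(cb, "")[[1]]
    if (!all(c(ch_a, ch_b) %in% acgt)) next
    if (ch_a[1] != ch_b[1] || ch_a[2] != ch_b[2]) next
    fam <- vapply(acgt, function(x) oracle_translate(paste0(ch_a[1], ch_a[2], x)),
                  character(1))
    if (length(unique(fam)) != 1L || any(fam == "*")) next
    purine <- function(b) b %in% c("A", "G")
    out[[length(out) + 1L]] <- data.frame(
      codon_column = i - 1L, base_a = ch_a[3], base_b = ch_b[3],
      is_transversion = ch_a[3] != ch_b[3] &&
        purine(ch_a[3]) != purine(ch_b[3])
    )
  }
  if (length(out) == 0L) {
    return(data.frame(codon_column = integer(0), base_a = character(0),
                      base_b = character(0), is_transversion = logical(0)))
  }
  do.call(rbind, out)
}

# N50 straight from the definition
oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (acc >= half) return(l)
  }
}

oracle_filter_hits <- function(hits, min_ratio = 0.5, min_identity = 0.5) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- !(hits$aligned_ratio[i] < min_ratio) &&
      !(hits$identity[i] < min_identity)
  }
  hits[keep, , drop = FALSE]
}

# exhaustive pairwise grouping: iterate merges until a fixed point
oracle_remove_redundant <- function(hits, overlap_frac = 0.5) {
  n <- nrow(hits)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || grp[i] == grp[j]) next
      if (hits$target_scaffold[i] != hits$target_scaffold[j]) next
      ov <- min(hits$target_end[i], hits$target_end[j]) -
        max(hits$target_start[i], hits$target_start[j]) + 1
      li <- hits$target_end[i] - hits$target_start[i] + 1
      lj <- hits$target_end[j] - hits$target_start[j] + 1
      if (ov > 0 && ov / li >= overlap_frac && ov / lj >= overlap_frac) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    o <- order(-hits$score[idx], hits$target_start[idx], hits$query_id[idx])
    keep <- c(keep, idx[o[1]])
  }
  hits[sort(keep), , drop = FALSE]
}

# exhaustive search over all monotonic gap-bounded subsequences (n <= ~10)
oracle_best_chain_size <- function(a, b, max_gap) {
  n <- length(a)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    k <- length(idx)
    if (k <= best) next
    idx <- idx[order(a[idx], b[idx])]
    da <- diff(a[idx])
    db <- diff(b[idx])
    ok_plus <- all(da >= 1 & da <= max_gap) && all(db >= 1 & db <= max_gap)
    ok_minus <- all(da >= 1 & da <= max_gap) && all(-db >= 1 & -db <= max_gap)
    if (ok_plus || ok_minus || k == 1L) best <- k
  }
  best
}

oracle_bin_counts <- function(values, bin_width) {
  counts <- list()
  for (v in values) {
    key <- as.character(floor(v / bin_width))
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  counts
}

# random helpers used across suites
random_fourfold_alignment <- function(n_codons, p_gap = 0.05, p_n = 0.02) {
  code <- standard_genetic_code()
  acgt <- c("A", "C", "G", "T")
  all_prefix <- unique(substr(names(code$codon_to_aa), 1, 2))
  mk_codon <- function(prefix) paste0(prefix, sample(acgt, 1))
  a <- character(n_codons)
  b <- character(n_codons)
  for (i in seq_len(n_codons)) {
    pa <- sample(all_prefix, 1)
    pb <- if (stats::runif(1) < 0.8) pa else sample(all_prefix, 1)
    ca <- mk_codon(pa)
    cb <- mk_codon(pb)
    if (stats::runif(1) < p_n) substr(ca, sample(1:3, 1), sample(1:3, 1)) <- "N"
    if (stats::runif(1) < p_gap) {
      ca <- "---"
    } else if (stats::runif(1) < p_gap) {
      cb <- "---"
    }
    a[i] <- ca
    b[i] <- cb
  }
  codon_pair_alignment(paste(a, collapse = ""), paste(b, collapse = ""))
}

random_hits <- function(n) {
  st <- sample.int(300, n, replace = TRUE)
  data.frame(
    query_id = sprintf("q%02d", sample.int(n, n)),
    target_id = sprintf("t%02d", seq_len(n)),
    target_scaffold = sample(c("s1", "s2"), n, replace = TRUE),
    target_start = st,
    target_end = st + sample.int(80, n, replace = TRUE),
    aligned_ratio = round(stats::runif(n), 2),
    identity = round(stats::runif(n), 2),
    score = sample.int(100, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
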