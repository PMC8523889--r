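#' HKY85 substitution model
#'
#' Nucleotide substitution model with stationary base frequencies `pi` and a
#' transition/transversion rate ratio `kappa`. The rate matrix has
#' off-diagonal entries `kappa * pi_j` for transitions and `pi_j` for
#' transversions, rows summing to zero, scaled so the mean substitution rate
#' at stationarity is 1 (branch lengths in expected substitutions per site).
#'
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param pi Stationary frequencies `(A, C, G, T)`, all `> 0`, summing to 1.
#' @return Object of class `hky_model`.
#' @export
hky_model <- function(kappa = 2, pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(kappa > 0, length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  names(pi) <- c("A", "C", "G", "T")
  structure(list(kappa = kappa, pi = pi), class = "hky_model")
}

# Unscaled HKY rate matrix, then normalized to mean rate 1
hky_rate_matrix <- function(model) {
  pi <- model$pi
  k <- model$kappa
  ts <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  ts["A", "G"] <- ts["G", "A"] <- ts["C", "T"] <- ts["T", "C"] <- 1
  R <- outer(rep(1, 4), pi) * ifelse(ts == 1, k, 1)
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  mu <- -sum(pi * diag(R))
  R / mu
}

#' HKY transition probability matrix
#'
#' `P(t) = exp(Q t)` for the scaled HKY rate matrix, computed by
#' eigendecomposition of the reversibility-symmetrised matrix
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is exact and numerically
#' stable for a reversible model. Rows sum to 1 and `pi %*% P == pi`.
#'
#' @param model An [hky_model()].
#' @param t Branch length in expected substitutions per site, `>= 0`.
#' @return 4x4 row-stochastic matrix, rows/columns ordered A, C, G, T.
#' @export
hky_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "hky_model"), t >= 0)
  Q <- hky_rate_matrix(model)
  sp <- sqrt(model$pi)
  S <- (Q * outer(sp, 1 / sp))
  S <- (S + t(S)) / 2  # symmetric up to rounding
  e <- eigen(S, symmetric = TRUE)
  P <- outer(1 / sp, sp) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(names(model$pi), names(model$pi))
  P
}

# Evolve integer-coded bases (1..4 = A,C,G,T) one branch under P
evolve_bases <- function(bases, P) {
  out <- integer(length(bases))
  for (b in 1:4) {
    idx <- which(bases == b)
    if (length(idx)) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  out
}

#' Simulate paralogous codon-pair alignments at a target corrected 4dTv
#'
#' Ancestral sequences are built from fourfold-degenerate codon families
#' (prefix drawn uniformly from the eight families, third base from the
#' model's stationary frequencies); the first two codon positions are held
#' fixed so family membership — and hence 4d-site status — is conserved,
#' isolating the third-position process the statistic measures. Third
#' positions of the two descendants evolve independently for half the total
#' divergence each, where the total divergence is solved numerically so the
#' expected corrected 4dTv equals `d_target`. Alignments are gap-free and
#' byte-deterministic under `seed`.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons (all fourfold-degenerate) per sequence.
#' @param d_target Target expected corrected 4dTv, `>= 0`.
#' @param model An [hky_model()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param id_prefix Prefix for pair identifiers.
#' @return List of [codon_pair_alignment()] objects.
#' @export
simulate_pair_set <- function(n_pairs, n_codons, d_target,
                              model = hky_model(), seed = NULL,
                              id_prefix = "pair") {
  if (!is.null(seed)) set.seed(seed)
  t_total <- solve_branch_length(model, d_target)
  P <- hky_transition_matrix(model, t_total / 2)
  code <- standard_genetic_code()
  acgt <- c("A", "C", "G", "T")
  lapply(seq_len(n_pairs), function(i) {
    prefix <- sample(code$fourfold_prefixes, n_codons, replace = TRUE)
    anc <- sample.int(4L, n_codons, replace = TRUE, prob = model$pi)
    s1 <- if (d_target == 0) anc else evolve_bases(anc, P)
    s2 <- if (d_target == 0) anc else evolve_bases(anc, P)
    a <- paste0(prefix, acgt[s1], collapse = "")
    b <- paste0(prefix, acgt[s2], collapse = "")
    codon_pair_alignment(a, b,
                         id_a = sprintf("%s%04d_a", id_prefix, i),
                         id_b = sprintf("%s%04d_b", id_prefix, i))
  })
}

#' Simulate a paralogome: a WGD burst plus background duplicate pairs
#'
#' Emulates a self-alignment paralog set in which a whole-genome duplication
#' deposited a burst of pairs at a common divergence, on top of a background
#' of small-scale duplicates of assorted ages. Labels are retained so peak
#' recovery can be scored against the truth.
#'
#' @param n_wgd Pairs from the duplication burst, at corrected 4dTv `wgd_d`.
#' @param n_background Background pairs, divergences uniform in
#'   `background_d_range`.
#' @param wgd_d Corrected 4dTv of the burst.
#' @param background_d_range Interval (length 2) of background divergences.
#' @param n_codons Codons per sequence.
#' @param model An [hky_model()].
#' @param seed Integer seed.
#' @return List with `alignments` (list of pair alignments) and `labels`
#'   (character, `"wgd"` or `"background"`, parallel to `alignments`).
#' @export
simulate_paralogome <- function(n_wgd, n_background, wgd_d,
                                background_d_range = c(0.1, 0.6),
                                n_codons = 500, model = hky_model(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wgd <- simulate_pair_set(n_wgd, n_codons, wgd_d, model,
                           seed = NULL, id_prefix = "wgd")
  bg <- list()
  if (n_background > 0) {
    d_bg <- stats::runif(n_background, background_d_range[1],
                         background_d_range[2])
    bg <- lapply(seq_len(n_background), function(i) {
      simulate_pair_set(1, n_codons, d_bg[i], model, seed = NULL,
                        id_prefix = sprintf("bg%04d_", i))[[1]]
    })
  }
  list(alignments = c(wgd, bg),
       labels = c(rep("wgd", n_wgd), rep("background", n_background)))
}

#' Simulate a k-mer depth histogram
#'
#' Main component: `genome_size` distinct k-mers with depths drawn
#' Poisson(`mean_depth`). Error component: `error_kmer_count` k-mers with
#' depths drawn geometric (success `error_p`) starting at 1, emulating
#' low-depth sequencing-error k-mers. Aggregated to (depth, count) rows.
#'
#' @param genome_size Number of distinct genomic k-mers (proxy for genome
#'   size in bp).
#' @param mean_depth Mean sequencing depth per k-mer.
#' @param k K-mer length (metadata only).
#' @param error_kmer_count Number of error k-mers.
#' @param error_p Geometric success parameter for error depths.
#' @param seed Integer seed.
#' @return Object of class `kmer_histogram`: list with `k` and `rows`
#'   (data frame `depth`, `count`, strictly increasing depth).
#' @export
simulate_kmer_histogram <- function(genome_size, mean_depth, k = 17,
                                    error_kmer_count = 0, error_p = 0.7,
                                    seed = NULL) {
  stopifnot(genome_size > 0, mean_depth > 0)
  if (!is.null(seed)) set.seed(seed)
  depths <- stats::rpois(genome_size, mean_depth)
  depths <- depths[depths > 0]
  if (error_kmer_count > 0) {
    err <- stats::rgeom(error_kmer_count, error_p) + 1L
    depths <- c(depths, err)
  }
  tab <- tabulate(depths)
  nz <- which(tab > 0)
  kmer_histogram(k = k, depth = nz, count = tab[nz])
}

#' Simulate pseudogenized gene copies with known lesions
#'
#' Each reference receives zero or one lesion: a premature stop (an internal
#' codon replaced by TGA), a frameshift (1-2 bp deletion, rendered as a gap
#' run in the candidate row), or a missing region (deletion of
#' `>= min_missing_codons` whole codons). Labels are retained so classifier
#' sensitivity and specificity can be computed exactly.
#'
#' @param references Character vector of reference CDS (no internal stops;
#'   see [random_cds()]).
#' @param lesion_probs Named numeric: probabilities for `stop`, `frameshift`,
#'   `missing`; remainder is intact.
#' @param min_missing_codons Minimum codons removed by a `missing` lesion.
#' @param seed Integer seed.
#' @return List with `candidates` (list of [codon_pair_alignment()],
#'   reference in row a, candidate in row b) and `labels` (character:
#'   `"intact"`, `"stop"`, `"frameshift"`, `"missing"`).
#' @export
simulate_pseudogenes <- function(references,
                                 lesion_probs = c(stop = 0.25,
                                                  frameshift = 0.25,
                                                  missing = 0.25),
                                 min_missing_codons = 30, seed = NULL) {
  stopifnot(all(names(lesion_probs) %in% c("stop", "frameshift", "missing")),
            sum(lesion_probs) <= 1)
  if (!is.null(seed)) set.seed(seed)
  types <- c("intact", names(lesion_probs))
  probs <- c(1 - sum(lesion_probs), unname(lesion_probs))
  labels <- sample(types, length(references), replace = TRUE, prob = probs)
  candidates <- vector("list", length(references))
  for (i in seq_along(references)) {
    ref <- toupper(references[[i]])
    n_cod <- nchar(ref) %/% 3L
    stopifnot(n_cod > min_missing_codons + 4)
    cand <- ref
    if (labels[i] == "stop") {
      at <- sample(2:(n_cod - 2L), 1)  # internal, not start/terminal codon
      substr(cand, 3 * at - 2, 3 * at) <- "TGA"
    } else if (labels[i] == "frameshift") {
      len <- sample(1:2, 1)
      at <- sample(4:(nchar(ref) - 6L), 1)
      substr(cand, at, at + len - 1L) <- strrep("-", len)
    } else if (labels[i] == "missing") {
      m <- min_missing_codons + sample(0:5, 1)
      at <- sample(2:(n_cod - m - 1L), 1)  # codon index of run start
      substr(cand, 3 * at - 2, 3 * (at + m - 1L)) <- strrep("-", 3 * m)
    }
    candidates[[i]] <- codon_pair_alignment(
      ref, cand, id_a = sprintf("ref%03d", i), id_b = sprintf("cand%03d", i)
    )
  }
  list(candidates = candidates, labels = labels)
}

#' Random intact coding sequence
#'
#' `ATG`, then `n_codons - 2` random non-stop codons, then `TAA`.
#'
#' @param n_codons Total codon count including start and terminal stop.
#' @return Uppercase CDS string with no internal stop codons.
#' @export
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  code <- standard_genetic_code()
  pool <- setdiff(names(code$codon_to_aa), code$stop_codons)
  paste0("ATG",
         paste(sample(pool, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Simulate gene-order anchor pairs with planted collinear blocks
#'
#' Plants `n_blocks` monotonic, gap-bounded runs of anchors (random
#' orientation, per-step gaps uniform in 1..`max_step`) on a pair of gene
#' orders, then adds uniform noise anchors. Ground-truth block membership is
#' retained.
#'
#' @param n_blocks Number of planted blocks.
#' @param anchors_per_block Anchors in each planted block.
#' @param n_noise Uniform random noise anchors.
#' @param genome_length Gene count per genome (both genomes).
#' @param max_step Maximum per-step index gap within a planted block.
#' @param seed Integer seed.
#' @return List with `anchors` (data frame `scaffold_a`, `gene_a_index`,
#'   `scaffold_b`, `gene_b_index`, 0-based indices) and `block_of` (integer
#'   vector, planted block id per anchor row, `NA` for noise).
#' @export
simulate_anchors <- function(n_blocks, anchors_per_block, n_noise,
                             genome_length = 200, max_step = 3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  block_of <- integer(0)
  for (b in seq_len(n_blocks)) {
    span <- anchors_per_block * max_step + 1L
    a0 <- sample.int(max(1L, genome_length - span), 1) - 1L
    b0 <- sample.int(max(1L, genome_length - span), 1) - 1L
    ori <- sample(c(1L, -1L), 1)
    da <- cumsum(c(0L, sample.int(max_step, anchors_per_block - 1L,
                                  replace = TRUE)))
    db <- cumsum(c(0L, sample.int(max_step, anchors_per_block - 1L,
                                  replace = TRUE)))
    ai <- a0 + da
    bi <- if (ori == 1L) b0 + db else (b0 + span) - db
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_a = "sA", gene_a_index = ai,
      scaffold_b = "sB", gene_b_index = bi
    )
    block_of <- c(block_of, rep(b, anchors_per_block))
  }
  if (n_noise > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_a = "sA",
      gene_a_index = sample.int(genome_length, n_noise, replace = TRUE) - 1L,
      scaffold_b = "sB",
      gene_b_index = sample.int(genome_length, n_noise, replace = TRUE) - 1L
    )
    block_of <- c(block_of, rep(NA_integer_, n_noise))
  }
  anchors <- do.call(rbind, rows)
  if (is.null(anchors)) {
    anchors <- data.frame(scaffold_a = character(0),
                          gene_a_index = integer(0),
                          scaffold_b = character(0),
                          gene_b_index = integer(0))
  }
  list(anchors = anchors, block_of = block_of)
}
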