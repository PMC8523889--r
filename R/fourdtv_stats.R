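#' Pooled base frequencies at fourfold-degenerate third positions
#'
#' Frequencies of A, C, G, T among all `2 * n4` third-position bases of the
#' site list (both sequences pooled). These are the frequency inputs to the
#' HKY transversion-distance correction, estimated per pair so the statistic
#' is self-contained.
#'
#' @param sites Site table from [extract_4d_sites()].
#' @return Named numeric vector `(A, C, G, T)` summing to 1.
#' @export
pooled_base_freqs <- function(sites) {
  if (nrow(sites) == 0L) stop("no 4d sites")
  acgt <- c("A", "C", "G", "T")
  tab <- table(factor(c(sites$base_a, sites$base_b), levels = acgt))
  stats::setNames(as.numeric(tab) / sum(tab), acgt)
}

#' Raw 4dTv: transversion proportion at fourfold-degenerate sites
#'
#' @param sites Site table from [extract_4d_sites()].
#' @return `Q = n_tv / n4`, the fraction of sites whose third-position bases
#'   differ by a transversion.
#' @export
raw_4dtv <- function(sites) {
  if (nrow(sites) == 0L) stop("no 4d sites")
  sum(sites$is_transversion) / nrow(sites)
}

#' HKY transversion-distance correction
#'
#' Corrects an observed transversion proportion for multiple hits under a
#' substitution model with unequal base frequencies:
#' `d = -2 * piR * piY * log(1 - Q / (2 * piR * piY))`,
#' where `piR`, `piY` are the purine and pyrimidine frequencies. At equal
#' frequencies (`piR = piY = 1/2`) this reduces to the Kimura two-parameter
#' transversion distance `-0.5 * log(1 - 2 Q)`.
#'
#' @param Q Observed transversion proportion in `[0, 1)`.
#' @param piR,piY Purine / pyrimidine frequencies, `piR + piY = 1`.
#' @return Corrected distance `d >= Q`, or `NA_real_` when the proportion is
#'   saturated (`Q >= 2 * piR * piY`), where the logarithm has no argument.
#' @examples
#' hky_correct(0.3, 0.5, 0.5)  # -0.5 * log(0.4)
#' @export
hky_correct <- function(Q, piR, piY) {
  stopifnot(Q >= 0, Q <= 1, piR > 0, piY > 0)
  if (abs(piR + piY - 1) > 1e-8) stop("piR + piY must equal 1")
  c2 <- 2 * piR * piY
  if (Q >= c2) return(NA_real_)
  -c2 * log(1 - Q / c2)
}

#' Per-pair 4dTv statistics
#'
#' Composite of site extraction, pooled frequency estimation, raw 4dTv and
#' the HKY correction. Degenerate pairs never raise: a pair without
#' fourfold-degenerate columns gets status `"no_sites"`, a pair whose
#' transversion proportion exceeds the correctable range gets `"saturated"`;
#' both are excluded from distributions downstream.
#'
#' @param aln A [codon_pair_alignment()].
#' @param code Genetic code.
#' @param pair_id Identifier; defaults to `"id_a|id_b"`.
#' @return Object of class `pair_stats`: list with `pair_id`, `n4`, `n_tv`,
#'   `Q`, `pi` (A,C,G,T), `piR`, `piY`, `d_corrected`, `status`.
#' @export
pair_4dtv <- function(aln, code = standard_genetic_code(),
                      pair_id = paste(aln$id_a, aln$id_b, sep = "|")) {
  sites <- extract_4d_sites(aln, code)
  if (nrow(sites) == 0L) {
    return(structure(
      list(pair_id = pair_id, n4 = 0L, n_tv = 0L, Q = NA_real_,
           pi = stats::setNames(rep(NA_real_, 4), c("A", "C", "G", "T")),
           piR = NA_real_, piY = NA_real_, d_corrected = NA_real_,
           status = "no_sites"),
      class = "pair_stats"
    ))
  }
  pi <- pooled_base_freqs(sites)
  piR <- pi[["A"]] + pi[["G"]]
  piY <- pi[["C"]] + pi[["T"]]
  Q <- raw_4dtv(sites)
  if (piR <= 0 || piY <= 0) {
    d <- if (Q == 0) 0 else NA_real_
  } else {
    d <- hky_correct(Q, piR, piY)
  }
  structure(
    list(pair_id = pair_id, n4 = nrow(sites),
         n_tv = as.integer(sum(sites$is_transversion)), Q = Q, pi = pi,
         piR = piR, piY = piY, d_corrected = d,
         status = if (is.na(d)) "saturated" else "ok"),
    class = "pair_stats"
  )
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("pair %s: n4 = %d, Q = %s, d = %s [%s]\n", x$pair_id, x$n4,
              format(x$Q, digits = 4), format(x$d_corrected, digits = 4),
              x$status))
  invisible(x)
}

#' Batch 4dTv over a list of pair alignments
#'
#' @param alignments List of [codon_pair_alignment()] objects.
#' @param code Genetic code.
#' @return Data frame, one row per pair: `pair_id`, `seq_a`, `seq_b` (row
#'   ids), `n4`, `n_tv`, `Q`, `piA`..`piT`, `d_corrected`, `status`.
#' @export
batch_4dtv <- function(alignments, code = standard_genetic_code()) {
  rows <- lapply(alignments, function(aln) {
    st <- pair_4dtv(aln, code)
    data.frame(
      pair_id = st$pair_id, seq_a = aln$id_a, seq_b = aln$id_b,
      n4 = st$n4, n_tv = st$n_tv, Q = st$Q,
      piA = st$pi[["A"]], piC = st$pi[["C"]],
      piG = st$pi[["G"]], piT = st$pi[["T"]],
      d_corrected = st$d_corrected, status = st$status,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a per-pair 4dTv table as TSV
#'
#' Tab-separated, header line, floats with 6 decimals, `.` decimal separator.
#'
#' @param stats Data frame from [batch_4dtv()].
#' @param path Output path.
#' @export
write_pair_stats <- function(stats, path) {
  num <- vapply(stats, is.numeric, logical(1)) &
    !vapply(stats, is.integer, logical(1))
  out <- stats
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expected corrected 4dTv under an HKY model at a given divergence
#'
#' The expected transversion proportion between two sequences separated by
#' total pairwise divergence `t` (expected substitutions per third-position
#' site) is `Q(t) = sum_i pi_i * sum_{j in tv(i)} P_ij(t)` from the model's
#' transition matrix; the expectation of the corrected statistic is then
#' `hky_correct(Q(t))` with the model's stationary purine/pyrimidine
#' frequencies. Strictly increasing in `t`.
#'
#' @param model An [hky_model()].
#' @param t Total pairwise divergence, `t >= 0`.
#' @return Expected corrected 4dTv.
#' @export
expected_4dtv <- function(model, t) {
  stopifnot(t >= 0)
  P <- hky_transition_matrix(model, t)
  tv <- transversion_mask()
  Q <- sum(model$pi * rowSums(P * tv))
  piR <- model$pi[["A"]] + model$pi[["G"]]
  piY <- model$pi[["C"]] + model$pi[["T"]]
  hky_correct(Q, piR, piY)
}

# 4x4 logical mask: TRUE where the i->j change is a transversion
transversion_mask <- function() {
  acgt <- c("A", "C", "G", "T")
  purine <- acgt %in% c("A", "G")
  outer(purine, purine, `!=`) * 1
}

#' Solve the pairwise divergence giving a target corrected 4dTv
#'
#' Inverts [expected_4dtv()] by bisection to absolute tolerance `1e-9` on the
#' returned distance. Used by the simulators to calibrate branch lengths.
#'
#' @param model An [hky_model()].
#' @param d_target Target corrected 4dTv, `>= 0`.
#' @param t_max Upper bracket for the search (expanded automatically).
#' @return Total pairwise divergence `t` with
#'   `expected_4dtv(model, t) == d_target` to `1e-9`.
#' @export
solve_branch_length <- function(model, d_target, t_max = 10) {
  stopifnot(d_target >= 0)
  if (d_target == 0) return(0)
  hi <- t_max
  for (i in 1:60) {
    v <- expected_4dtv(model, hi)
    if (!is.na(v) && v >= d_target) break
    hi <- hi * 2
    if (hi > 1e6) stop("unreachable divergence: d_target = ", d_target)
  }
  if (is.na(expected_4dtv(model, hi))) {
    stop("unreachable divergence: d_target = ", d_target,
         " is at or beyond saturation")
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- expected_4dtv(model, mid)
    if (is.na(v) || v > d_target) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  mid <- (lo + hi) / 2
  if (abs(expected_4dtv(model, mid) - d_target) > 1e-6) {
    stop("unreachable divergence: d_target = ", d_target)
  }
  mid
}
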