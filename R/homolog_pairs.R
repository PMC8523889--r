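#' Filter homology hits on aligned ratio and identity
#'
#' Retains hits with `aligned_ratio >= min_ratio` and
#' `identity >= min_identity`; the thresholds exclude strictly smaller
#' values, so equality passes. Order is preserved.
#'
#' @param hits Data frame with at least `aligned_ratio` and `identity`
#'   columns, both proportions in `[0, 1]`.
#' @param min_ratio Minimum aligned query fraction (default 0.5).
#' @param min_identity Minimum identity proportion (default 0.5).
#' @return Filtered data frame.
#' @export
filter_hits <- function(hits, min_ratio = 0.5, min_identity = 0.5) {
  stopifnot(all(c("aligned_ratio", "identity") %in% names(hits)))
  stopifnot(all(hits$aligned_ratio >= 0 & hits$aligned_ratio <= 1),
            all(hits$identity >= 0 & hits$identity <= 1))
  out <- hits[hits$aligned_ratio >= min_ratio &
                hits$identity >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove redundant hits by reciprocal-overlap grouping
#'
#' Hits on the same target scaffold whose intervals reciprocally overlap by
#' at least `overlap_frac` of each interval's length are grouped (groups are
#' the connected components of that pairwise relation); only the
#' highest-score hit per group is retained, ties broken by smaller
#' `target_start`, then lexicographically smaller `query_id`. Coordinates
#' are 1-based inclusive.
#'
#' @param hits Data frame with `query_id`, `target_scaffold`,
#'   `target_start`, `target_end`, `score`.
#' @param overlap_frac Reciprocal overlap threshold (default 0.5).
#' @return Data frame of retained hits, in original row order.
#' @export
remove_redundant <- function(hits, overlap_frac = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  stopifnot(all(hits$target_start <= hits$target_end))
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (hits$target_scaffold[i] != hits$target_scaffold[j]) next
      ov <- min(hits$target_end[i], hits$target_end[j]) -
        max(hits$target_start[i], hits$target_start[j]) + 1
      if (ov <= 0) next
      len_i <- hits$target_end[i] - hits$target_start[i] + 1
      len_j <- hits$target_end[j] - hits$target_start[j] + 1
      if (ov / len_i >= overlap_frac && ov / len_j >= overlap_frac) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    o <- order(-hits$score[idx], hits$target_start[idx], hits$query_id[idx])
    keep[idx[o[1]]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a homology hit table from TSV
#'
#' Tab-separated with a header line and the `AlignmentHit` columns
#' (`query_id`, `target_id`, `target_scaffold`, `target_start`,
#' `target_end`, `aligned_ratio`, `identity`, `score`). Identity is accepted
#' on the 0-1 or the 0-100 scale, auto-detected by values greater than 1 and
#' normalised to 0-1.
#'
#' @param path Input path.
#' @return Data frame of hits.
#' @export
read_hits_tsv <- function(path) {
  hits <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE)
  if (any(hits$identity > 1)) hits$identity <- hits$identity / 100
  hits
}

# Longest monotonic gap-bounded chain by dynamic programming.
# a, b: 0-based indices sorted by a; direction +1 / -1 for b.
# Returns integer positions (into a/b) of the best chain, or integer(0).
chain_dp <- function(a, b, direction, max_gap) {
  n <- length(a)
  if (n == 0L) return(integer(0))
  best <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- a[j] - a[i]
      db <- direction * (b[j] - b[i])
      if (da >= 1 && da <= max_gap && db >= 1 && db <= max_gap &&
          best[i] + 1L > best[j]) {
        best[j] <- best[i] + 1L
        prev[j] <- i
      }
    }
  }
  end <- which.max(best)
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- prev[end]
  }
  chain
}

#' Chain anchor pairs into collinear blocks
#'
#' A simplified collinearity finder: within each scaffold pair, maximal
#' chains of anchors monotonic in both gene orders (either orientation) with
#' per-step index gaps of at most `max_gap` in both genomes are found by
#' longest-chain dynamic programming; the best chain is emitted as a block,
#' its anchors removed, and the search repeated until no chain of at least
#' `min_anchors` anchors remains. Each anchor belongs to at most one block.
#'
#' @param anchors Data frame with `scaffold_a`, `gene_a_index`,
#'   `scaffold_b`, `gene_b_index` (0-based gene-order indices).
#' @param min_anchors Minimum anchors per emitted block (default 3).
#' @param max_gap Maximum per-step index gap in both genomes (default 15).
#' @return Data frame, one row per anchor of an emitted block: `block_id`,
#'   `orientation` (`"+"`/`"-"`), the anchor columns, and `score` (anchor
#'   count of the block). Empty data frame when no block qualifies.
#' @export
collinear_blocks <- function(anchors, min_anchors = 3, max_gap = 15) {
  empty <- data.frame(block_id = integer(0), orientation = character(0),
                      scaffold_a = character(0), gene_a_index = integer(0),
                      scaffold_b = character(0), gene_b_index = integer(0),
                      score = integer(0))
  if (nrow(anchors) == 0L) return(empty)
  out <- list()
  block_id <- 0L
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$scaffold_a, anchors$scaffold_b, sep = "\r"))
  for (grp in groups) {
    pool <- grp
    repeat {
      if (length(pool) < min_anchors) break
      ord <- pool[order(anchors$gene_a_index[pool],
                        anchors$gene_b_index[pool])]
      a <- anchors$gene_a_index[ord]
      b <- anchors$gene_b_index[ord]
      cp <- chain_dp(a, b, +1L, max_gap)
      cm <- chain_dp(a, b, -1L, max_gap)
      ori <- if (length(cp) >= length(cm)) "+" else "-"
      chain <- if (ori == "+") cp else cm
      if (length(chain) < min_anchors) break
      rows <- ord[chain]
      block_id <- block_id + 1L
      out[[block_id]] <- data.frame(
        block_id = block_id, orientation = ori,
        scaffold_a = anchors$scaffold_a[rows],
        gene_a_index = anchors$gene_a_index[rows],
        scaffold_b = anchors$scaffold_b[rows],
        gene_b_index = anchors$gene_b_index[rows],
        score = length(chain)
      )
      pool <- setdiff(pool, rows)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read an anchor table from TSV
#'
#' Columns `scaffold_a`, `gene_a_index`, `scaffold_b`, `gene_b_index`
#' (tab-separated, header line, `#` comments allowed); indices 0-based.
#'
#' @param path Input path.
#' @return Data frame of anchors.
#' @export
read_anchors_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write collinear blocks as TSV
#'
#' @param blocks A [collinear_blocks()] result.
#' @param path Output path.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
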