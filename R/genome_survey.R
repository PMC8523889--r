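#' K-mer depth histogram
#'
#' @param k K-mer length.
#' @param depth Positive integer depths, strictly increasing.
#' @param count Nonnegative counts, one per depth.
#' @return Object of class `kmer_histogram`.
#' @export
kmer_histogram <- function(k, depth, count) {
  stopifnot(length(depth) == length(count), all(depth >= 1),
            all(count >= 0), !is.unsorted(depth, strictly = TRUE))
  structure(list(k = k,
                 rows = data.frame(depth = as.numeric(depth),
                                   count = as.numeric(count))),
            class = "kmer_histogram")
}

#' Read a k-mer histogram from TSV
#'
#' Two tab-separated columns `depth`, `count`, no header; `#` comment lines
#' allowed.
#'
#' @param path Input path.
#' @param k K-mer length to record (default 17).
#' @return A [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 17) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("depth", "count"))
  tab <- tab[order(tab$depth), , drop = FALSE]
  kmer_histogram(k, tab$depth, tab$count)
}

#' Modal k-mer depth with low-depth error-peak exclusion
#'
#' Sequencing errors produce an excess of low-depth k-mers that can dominate
#' the raw argmax. Scanning counts from the smallest depth, the first local
#' minimum separates the error component from the genomic component;
#' `K_depth` is the argmax of counts at depths strictly above that minimum.
#' When no local minimum exists the argmax is taken over all depths. Ties go
#' to the smaller depth.
#'
#' @param hist A [kmer_histogram()].
#' @return Modal depth `K_depth`.
#' @export
kmer_peak_depth <- function(hist) {
  rows <- hist$rows
  if (nrow(rows) == 0L || all(rows$count == 0)) stop("degenerate histogram")
  cnt <- rows$count
  n <- length(cnt)
  min_pos <- NA_integer_
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (cnt[i] <= cnt[i - 1L] && cnt[i] < cnt[i + 1L]) {
        min_pos <- i
        break
      }
    }
  }
  cand <- if (is.na(min_pos)) seq_len(n) else (min_pos + 1L):n
  best <- cand[which.max(cnt[cand])]  # which.max ties -> first = smaller depth
  rows$depth[best]
}

#' Total k-mer instances in a histogram
#'
#' @param hist A [kmer_histogram()].
#' @return `K_num = sum(depth * count)`.
#' @export
total_kmers <- function(hist) {
  sum(hist$rows$depth * hist$rows$count)
}

#' Genome size from k-mer statistics
#'
#' The standard k-mer survey estimator: `size_bp = K_num / K_depth`, the
#' total number of k-mer instances over the modal (expected) k-mer depth.
#'
#' @param K_num Total k-mer instances.
#' @param K_depth Modal k-mer depth, `> 0`.
#' @return Estimated genome size in bp (real-valued).
#' @examples
#' genome_size_estimate(40525178512, 23)  # ~1.76e9 bp, about 1.8 Gb
#' @export
genome_size_estimate <- function(K_num, K_depth) {
  if (K_depth <= 0) stop("invalid depth")
  K_num / K_depth
}

#' Full genome-size survey from a histogram
#'
#' @param hist A [kmer_histogram()].
#' @return List with `K_num`, `K_depth`, `size_bp` and `size_gb` (size in Gb
#'   rounded to one decimal, the precision such surveys are quoted at).
#' @export
survey_genome_size <- function(hist) {
  K_num <- total_kmers(hist)
  K_depth <- kmer_peak_depth(hist)
  size <- genome_size_estimate(K_num, K_depth)
  list(K_num = K_num, K_depth = K_depth, size_bp = size,
       size_gb = round_half_up(size / 1e9, 1))
}

#' Assembly summary statistics
#'
#' N50 is the length of the sequence at which the cumulative length, taken
#' in descending length order, first reaches half the total. GC fraction is
#' computed over unambiguous (A,C,G,T) bases.
#'
#' @param sequences Named character vector of sequences, or a path to a
#'   FASTA file.
#' @param min_length Sequences shorter than this are excluded (default 100).
#' @return List of class `assembly_stats`: `n_sequences`, `total_length_bp`,
#'   `N50_bp`, `longest_bp`, `gc_fraction`.
#' @export
assembly_stats <- function(sequences, min_length = 100) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  lens <- unname(nchar(sequences))
  keep <- lens >= min_length
  if (!any(keep)) stop("no sequences of length >= ", min_length)
  seqs <- toupper(sequences[keep])
  lens <- lens[keep]
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seqs) {
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T")))
    counts <- counts + as.numeric(tab)
  }
  gc <- (counts[["G"]] + counts[["C"]]) / sum(counts)
  structure(list(n_sequences = length(seqs), total_length_bp = total,
                 N50_bp = n50, longest_bp = max(lens), gc_fraction = gc),
            class = "assembly_stats")
}

# half-up rounding (R's round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percentage with half-up rounding
#'
#' `round(100 * part / whole, decimals)` with half-up rounding, the
#' convention used when quoting assembly coverage and BUSCO completeness.
#'
#' @param part,whole Numerator and denominator (`whole > 0`).
#' @param decimals Decimal places (default 1).
#' @return Percentage on the 0-100 scale.
#' @examples
#' percent_of(3536, 3640)  # 97.1
#' @export
percent_of <- function(part, whole, decimals = 1) {
  if (whole <= 0) stop("invalid denominator")
  round_half_up(100 * part / whole, decimals)
}

#' Gene-set accounting
#'
#' Splits an annotated gene set into orthogroup-clustered and unclustered
#' genes and checks the bookkeeping: the two must sum to the annotated
#' total.
#'
#' @param clustered,unclustered Gene counts.
#' @return List with `clustered`, `unclustered`, `total` and
#'   `clustered_pct` (percent of total, one decimal).
#' @export
gene_accounting <- function(clustered, unclustered) {
  stopifnot(clustered >= 0, unclustered >= 0)
  total <- clustered + unclustered
  list(clustered = clustered, unclustered = unclustered, total = total,
       clustered_pct = percent_of(clustered, total))
}
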