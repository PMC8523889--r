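#' Standard genetic code with fourfold-degenerate codon families
#'
#' Returns the standard nuclear genetic code together with the two pieces of
#' derived information the 4dTv statistic needs: the stop-codon set and the
#' eight dinucleotide prefixes (TC, CT, CC, CG, AC, GT, GC, GG) whose four
#' codons all encode the same amino acid, i.e. whose third position is
#' fourfold degenerate.
#'
#' @return A list with components `codon_to_aa` (named character vector of
#'   length 64, one-letter amino-acid symbols, `*` for stop), `stop_codons`
#'   (character vector of 3 triplets) and `fourfold_prefixes` (character
#'   vector of 8 dinucleotides).
#' @examples
#' code <- standard_genetic_code()
#' code$stop_codons
#' @export
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # amino acids in TCAG-major order, the classical codon-table layout
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  codon_to_aa <- stats::setNames(aa, codons)
  prefixes <- unique(substr(codons, 1, 2))
  fourfold <- prefixes[vapply(prefixes, function(p) {
    length(unique(codon_to_aa[paste0(p, bases)])) == 1L
  }, logical(1))]
  list(
    codon_to_aa = codon_to_aa,
    stop_codons = names(codon_to_aa)[codon_to_aa == "*"],
    fourfold_prefixes = fourfold
  )
}

#' Validate a coding sequence and record internal stop codons
#'
#' Strips gap symbols, checks the reading frame and records the 0-based codon
#' indices of in-frame stop codons occurring before the final codon. Internal
#' stops are recorded, not rejected: downstream pseudogene calling needs them,
#' and a terminal stop is ordinary.
#'
#' @param id Sequence identifier.
#' @param bases Nucleotide string over `A,C,G,T,N,-` (case-insensitive);
#'   gaps are removed before validation.
#' @return An object of class `coding_sequence`: a list with `id`, `bases`
#'   (uppercase, gap-free) and `internal_stop_positions` (0-based codon
#'   indices).
#' @examples
#' validate_cds("g2", "ATGTAAAAA")$internal_stop_positions  # 1
#' @export
validate_cds <- function(id, bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  s <- gsub("-", "", toupper(bases), fixed = TRUE)
  if (nchar(s) == 0L) stop("empty input: '", id, "'")
  if (nchar(s) %% 3L != 0L) {
    stop("frame error: '", id, "' has gap-free length ", nchar(s),
         ", not divisible by 3")
  }
  if (grepl("[^ACGTN]", s)) {
    stop("invalid base in '", id, "': only A,C,G,T,N allowed")
  }
  code <- standard_genetic_code()
  n_codons <- nchar(s) %/% 3L
  codons <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  internal <- which(codons[-n_codons] %in% code$stop_codons) - 1L
  structure(
    list(id = id, bases = s, internal_stop_positions = as.integer(internal)),
    class = "coding_sequence"
  )
}

#' Construct a codon pair alignment
#'
#' Houses two gap-aligned coding sequences with the frame anchored at
#' alignment column 0; codon columns are consecutive column triplets. Both
#' rows must have equal length divisible by 3 and use only `A,C,G,T,N,-`.
#' Per-row frame validity (gap-stripped length divisible by 3) is *not*
#' enforced: a row whose gap total is not a multiple of 3 is exactly a
#' frameshifted pseudogene candidate, which [classify_pseudogene()] must be
#' able to represent in order to flag it.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length, gap symbol
#'   `-` allowed.
#' @param id_a,id_b Row identifiers.
#' @return An object of class `codon_pair_alignment`.
#' @export
codon_pair_alignment <- function(seq_a, seq_b, id_a = "a", id_b = "b") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned lengths differ: ", nchar(seq_a), " vs ", nchar(seq_b))
  }
  if (nchar(seq_a) %% 3L != 0L) {
    stop("alignment length ", nchar(seq_a), " not divisible by 3")
  }
  if (nchar(seq_a) == 0L) stop("empty input")
  if (grepl("[^ACGTN-]", seq_a) || grepl("[^ACGTN-]", seq_b)) {
    stop("invalid base: alignment rows must use A,C,G,T,N,-")
  }
  structure(
    list(seq_a = seq_a, seq_b = seq_b, id_a = id_a, id_b = id_b,
         n_columns = nchar(seq_a) %/% 3L),
    class = "codon_pair_alignment"
  )
}

#' @export
print.codon_pair_alignment <- function(x, ...) {
  cat("codon pair alignment: ", x$id_a, " / ", x$id_b, ", ",
      x$n_columns, " codon columns\n", sep = "")
  invisible(x)
}

#' Extract fourfold-degenerate sites from a codon pair alignment
#'
#' A codon column yields a site iff (i) neither codon contains a gap or `N`,
#' (ii) the first two nucleotides are identical between the two sequences and
#' (iii) that shared dinucleotide prefix heads a fourfold-degenerate codon
#' family. Requiring identity at the first two positions in both sequences
#' guarantees both codons belong to the same synonymous family, so any
#' third-position difference is synonymous.
#'
#' @param aln A [codon_pair_alignment()].
#' @param code A genetic code from [standard_genetic_code()].
#' @return A data frame with one row per site, in column order: `codon_column`
#'   (0-based), `base_a`, `base_b` (third-position nucleotides) and
#'   `is_transversion`.
#' @export
extract_4d_sites <- function(aln, code = standard_genetic_code()) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  ca <- strsplit(aln$seq_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$seq_b, "", fixed = TRUE)[[1]]
  i1 <- seq(1L, length(ca), by = 3L)
  p1a <- ca[i1]; p2a <- ca[i1 + 1L]; p3a <- ca[i1 + 2L]
  p1b <- cb[i1]; p2b <- cb[i1 + 1L]; p3b <- cb[i1 + 2L]
  acgt <- c("A", "C", "G", "T")
  clean <- p1a %in% acgt & p2a %in% acgt & p3a %in% acgt &
    p1b %in% acgt & p2b %in% acgt & p3b %in% acgt
  keep <- clean & p1a == p1b & p2a == p2b &
    paste0(p1a, p2a) %in% code$fourfold_prefixes
  idx <- which(keep)
  data.frame(
    codon_column = idx - 1L,
    base_a = p3a[idx],
    base_b = p3b[idx],
    is_transversion = classify_change(p3a[idx], p3b[idx]) == "transversion",
    stringsAsFactors = FALSE
  )
}

#' Classify a nucleotide change as identical, transition or transversion
#'
#' Transitions stay within the purines `{A,G}` or the pyrimidines `{C,T}`;
#' transversions cross between the classes. Vectorised over both arguments.
#'
#' @param base_a,base_b Nucleotides in `{A,C,G,T}`.
#' @return Character vector over `"identical"`, `"transition"`,
#'   `"transversion"`.
#' @examples
#' classify_change("A", "G")  # transition
#' classify_change("A", "T")  # transversion
#' @export
classify_change <- function(base_a, base_b) {
  acgt <- c("A", "C", "G", "T")
  if (length(base_a) != length(base_b)) stop("length mismatch")
  if (length(base_a) == 0L) return(character(0))
  if (!all(base_a %in% acgt) || !all(base_b %in% acgt)) {
    stop("invalid base: arguments must be A, C, G or T")
  }
  purine_a <- base_a %in% c("A", "G")
  purine_b <- base_b %in% c("A", "G")
  out <- ifelse(base_a == base_b, "identical",
                ifelse(purine_a == purine_b, "transition", "transversion"))
  out
}
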