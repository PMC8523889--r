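# maximal gap runs per alignment row: data.frame(start, length), 1-based columns
gap_runs <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Classify pseudogene lesions on a reference/candidate codon alignment
#'
#' Tests the candidate row (row b) of a codon pair alignment against the
#' reference row (row a) for the three lesion classes that inactivate a gene
#' copy:
#' \describe{
#'   \item{premature stop}{an in-frame stop codon in the candidate (read in
#'     alignment-frame codon columns, gap-free triplets only) strictly
#'     before the reference's final codon column;}
#'   \item{frameshift}{any maximal gap run, in either row, whose length is
#'     not divisible by 3;}
#'   \item{missing region}{a candidate gap run spanning at least
#'     `min_missing_codons` codons, or candidate coverage of fewer than
#'     `min_coverage` of the reference's codon columns.}
#' }
#' The missing-region test is a coding-sequence reading of "missing exon
#' regions": genomic exon structure is not examined, only the aligned CDS.
#'
#' @param aln A [codon_pair_alignment()], reference in row a, candidate in
#'   row b.
#' @param code Genetic code.
#' @param min_missing_codons Gap-run threshold in codons (default 30).
#' @param min_coverage Minimum fraction of reference codon columns covered
#'   by the candidate (default 0.8).
#' @return Object of class `pseudogene_flags`: list with logical
#'   `premature_stop`, `frameshift`, `missing_exon`, `is_pseudogene` (their
#'   disjunction) and detail fields `stop_codon_index` (0-based codon
#'   column), `frameshift_column` (0-based alignment column),
#'   `missing_span` (codons) and `coverage`.
#' @export
classify_pseudogene <- function(aln, code = standard_genetic_code(),
                                min_missing_codons = 30,
                                min_coverage = 0.8) {
  stopifnot(inherits(aln, "codon_pair_alignment"))
  ca <- strsplit(aln$seq_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$seq_b, "", fixed = TRUE)[[1]]
  n_col <- length(ca) %/% 3L
  i1 <- seq(1L, length(ca), by = 3L)
  ref_cod <- paste0(ca[i1], ca[i1 + 1L], ca[i1 + 2L])
  cand_cod <- paste0(cb[i1], cb[i1 + 1L], cb[i1 + 2L])
  ref_full <- !grepl("-", ref_cod, fixed = TRUE)
  cand_full <- !grepl("-", cand_cod, fixed = TRUE)

  # the reference must be an intact gene: no in-frame stop before its final
  # codon column (checked in alignment frame so gapped references still work)
  ref_final <- max(which(ref_full))
  ref_stops <- which(ref_full & ref_cod %in% code$stop_codons)
  if (any(ref_stops < ref_final)) {
    stop("invalid reference: '", aln$id_a, "' contains internal stop codons")
  }

  # premature stop: candidate stop strictly before the reference's final codon
  stop_cols <- which(cand_full & cand_cod %in% code$stop_codons)
  stop_cols <- stop_cols[stop_cols < ref_final]
  premature_stop <- length(stop_cols) > 0L

  runs_a <- gap_runs(aln$seq_a)
  runs_b <- gap_runs(aln$seq_b)
  fs_runs <- rbind(runs_a, runs_b)
  fs_runs <- fs_runs[fs_runs$length %% 3L != 0L, , drop = FALSE]
  frameshift <- nrow(fs_runs) > 0L

  span_codons <- if (nrow(runs_b)) max(runs_b$length) %/% 3L else 0L
  coverage <- sum(cand_full & ref_full) / sum(ref_full)
  missing_exon <- span_codons >= min_missing_codons || coverage < min_coverage

  structure(list(
    premature_stop = premature_stop,
    stop_codon_index = if (premature_stop) stop_cols[1] - 1L else NA_integer_,
    frameshift = frameshift,
    frameshift_column = if (frameshift) min(fs_runs$start) - 1L else NA_integer_,
    missing_exon = missing_exon,
    missing_span = span_codons,
    coverage = coverage,
    is_pseudogene = premature_stop || frameshift || missing_exon
  ), class = "pseudogene_flags")
}

#' @export
print.pseudogene_flags <- function(x, ...) {
  lab <- c("premature_stop", "frameshift", "missing_exon")
  on <- lab[unlist(x[lab])]
  cat("pseudogene flags:",
      if (length(on)) paste(on, collapse = ", ") else "none (intact)", "\n")
  invisible(x)
}

#' Copy-number matrix over gene-model candidates
#'
#' Counts intact and pseudogenized loci per (query gene, species). Input
#' candidates are expected to be pre-filtered ([filter_hits()],
#' [remove_redundant()]) so each row is a distinct retained locus; rows with
#' a duplicated (gene, species, locus) key are counted once.
#'
#' @param candidates Data frame with `query_gene`, `species`, `locus_id` and
#'   logical `is_pseudogene`.
#' @return Data frame, one row per (query_gene, species): `intact_count`,
#'   `pseudogene_count`, `total`.
#' @export
copy_number_profile <- function(candidates) {
  stopifnot(all(c("query_gene", "species", "locus_id", "is_pseudogene")
                %in% names(candidates)))
  key <- paste(candidates$query_gene, candidates$species,
               candidates$locus_id, sep = "\r")
  cand <- candidates[!duplicated(key), , drop = FALSE]
  agg <- stats::aggregate(
    cbind(pseudogene_count = cand$is_pseudogene,
          intact_count = !cand$is_pseudogene),
    by = list(query_gene = cand$query_gene, species = cand$species),
    FUN = sum
  )
  agg$total <- agg$intact_count + agg$pseudogene_count
  agg <- agg[order(agg$query_gene, agg$species),
             c("query_gene", "species", "intact_count",
               "pseudogene_count", "total")]
  rownames(agg) <- NULL
  agg
}

#' Write a copy-number matrix as TSV
#'
#' Genes as rows, species as columns, cells formatted `"intact/pseudo"`.
#'
#' @param profile A [copy_number_profile()] result.
#' @param path Output path.
#' @export
write_copy_matrix <- function(profile, path) {
  genes <- sort(unique(profile$query_gene))
  species <- sort(unique(profile$species))
  m <- matrix("0/0", length(genes), length(species),
              dimnames = list(genes, species))
  for (r in seq_len(nrow(profile))) {
    m[profile$query_gene[r], profile$species[r]] <-
      sprintf("%d/%d", profile$intact_count[r], profile$pseudogene_count[r])
  }
  out <- data.frame(query_gene = genes, m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
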