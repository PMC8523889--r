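#' Read a FASTA file
#'
#' Wrapped or unwrapped records; sequences are normalised to uppercase.
#' Windows line endings are handled transparently.
#'
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("parse error: empty FASTA: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences as FASTA
#'
#' Uppercase, 60-column wrapped.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Write a pair-alignment list as 2-record aligned FASTA files
#'
#' One file per pair, named `<prefix><i>.fasta`, each with the two aligned
#' rows. A `#`-style provenance comment is not valid FASTA, so parameters
#' are instead recorded in the returned manifest.
#'
#' @param alignments List of [codon_pair_alignment()] objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Data frame manifest with `pair_id` and `path`.
#' @export
write_pair_fastas <- function(alignments, dir, prefix = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(alignments), function(i) {
    aln <- alignments[[i]]
    p <- file.path(dir, sprintf("%s%04d.fasta", prefix, i))
    write_fasta(stats::setNames(c(aln$seq_a, aln$seq_b),
                                c(aln$id_a, aln$id_b)), p)
    data.frame(pair_id = paste(aln$id_a, aln$id_b, sep = "|"), path = p)
  })
  do.call(rbind, rows)
}

#' Read a 2-record aligned FASTA as a codon pair alignment
#'
#' @param path Input path.
#' @return A [codon_pair_alignment()].
#' @export
read_pair_fasta <- function(path) {
  seqs <- read_fasta(path)
  if (length(seqs) != 2L) {
    stop("parse error: expected 2 aligned records in ", path,
         ", found ", length(seqs))
  }
  codon_pair_alignment(seqs[[1]], seqs[[2]],
                       id_a = names(seqs)[1], id_b = names(seqs)[2])
}

#' Restrict anchor pairs to collinear blocks
#'
#' The 4dTv distribution can be built either from all homolog pairs or only
#' from pairs anchored inside collinear (syntenic) blocks — the latter
#' restricts the signal to duplicated segments and is the default.
#'
#' @param anchors Anchor data frame (see [collinear_blocks()]).
#' @param within_blocks_only Keep only anchors assigned to a block
#'   (default `TRUE`).
#' @param min_anchors,max_gap Chaining parameters.
#' @return Anchor data frame (with `block_id`/`orientation` columns when
#'   restricted).
#' @export
select_4dtv_anchors <- function(anchors, within_blocks_only = TRUE,
                                min_anchors = 3, max_gap = 15) {
  if (!within_blocks_only) return(anchors)
  collinear_blocks(anchors, min_anchors = min_anchors, max_gap = max_gap)
}
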