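#' Pairwise sequence identity
#'
#' Identity is the number of columns where both sequences carry the same
#' non-gap amino acid, divided by the number of columns where at least one
#' sequence is non-gap. Columns gapped in both sequences are ignored; 'X'
#' counts as occupancy but never as a match. Returns 0 when no column is
#' occupied in either sequence.
#'
#' @param a,b aligned sequence strings of equal length
#' @return fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequence length mismatch")
  m <- encode_alignment(alignment(c("a", "b"), c(a, b)))
  identity_matrix_cpp(m)[1, 2]
}

#' All-vs-all identity matrix
#' @param aln an [alignment]
#' @return symmetric numeric matrix with unit diagonal
#' @export
identity_matrix <- function(aln) {
  identity_matrix_cpp(encode_alignment(aln))
}

#' Remove redundant sequences by greedy identity filtering
#'
#' Records are scanned in order; a record is kept iff its identity to every
#' previously kept record is `<= max_id` (first-seen wins). The operation is
#' idempotent.
#'
#' @param aln an [alignment]
#' @param max_id maximum allowed identity to any kept record, in (0, 1]
#' @return filtered [alignment], order preserved
#' @export
filter_redundant <- function(aln, max_id = 0.90) {
  if (!is.numeric(max_id) || length(max_id) != 1L || max_id <= 0 || max_id > 1)
    stop("max_id must lie in (0, 1]")
  keep <- greedy_filter_cpp(encode_alignment(aln), max_id)
  aln_subset(aln, keep)
}

#' Remove gap-rich columns
#'
#' Columns whose gap fraction exceeds `max_gap_frac` are removed. 'X' is not
#' a gap.
#'
#' @param aln an [alignment]
#' @param max_gap_frac maximum tolerated gap fraction per column
#' @return list with `alignment` (filtered) and `kept` (original 1-based
#'   indices of the retained columns, mapping new to old positions)
#' @export
filter_gappy_columns <- function(aln, max_gap_frac = 0.50) {
  if (!is.numeric(max_gap_frac) || max_gap_frac < 0 || max_gap_frac > 1)
    stop("max_gap_frac must lie in [0, 1]")
  m <- encode_alignment(aln)
  gap_frac <- colMeans(m == 21L)
  kept <- which(gap_frac <= max_gap_frac)
  if (length(kept) == 0L) stop("all columns exceed the gap threshold")
  list(alignment = aln_select_columns(aln, kept), kept = kept)
}

#' Sequence reweighting and effective sequence number
#'
#' Each record's weight is 1 over the number of records (itself included)
#' within `id_threshold` identity of it; Neff is the sum of the weights.
#'
#' @param aln an [alignment]
#' @param id_threshold identity threshold in (0, 1)
#' @return object of class `coevo_weights`: list with `weights`, `neff`,
#'   `id_threshold`
#' @export
sequence_weights <- function(aln, id_threshold = 0.80) {
  if (nseq(aln) == 0L) stop("empty alignment")
  if (!is.numeric(id_threshold) || id_threshold <= 0 || id_threshold >= 1)
    stop("id_threshold must lie in (0, 1)")
  w <- seq_weights_cpp(encode_alignment(aln), id_threshold)
  neff <- sum(w)
  stopifnot(neff >= 1 - 1e-9, neff <= nseq(aln) + 1e-9)
  structure(list(weights = w, neff = neff, id_threshold = id_threshold),
            class = "coevo_weights")
}

#' @export
print.coevo_weights <- function(x, ...) {
  cat(sprintf("<weights: %d records, neff = %.2f at %.0f%% identity>\n",
              length(x$weights), x$neff, 100 * x$id_threshold))
  invisible(x)
}

#' Nf alignment-depth score
#'
#' Nf = Neff / sqrt(L). Alignments with Nf > 64 are heuristically expected
#' to yield coevolution contacts accurate enough for structure modeling.
#'
#' @param neff effective number of sequences (> 0)
#' @param ncols alignment length L (> 0)
#' @return Nf
#' @export
compute_nf <- function(neff, ncols) {
  if (!is.numeric(neff) || neff <= 0) stop("neff must be positive")
  if (!is.numeric(ncols) || ncols <= 0) stop("ncols must be positive")
  neff / sqrt(ncols)
}

#' Locate the alignment column of a reference residue
#'
#' Maps a residue number of a reference (ungapped) sequence through its gap
#' pattern to the corresponding alignment column.
#'
#' @param aln an [alignment]
#' @param ref_id id of the reference record
#' @param ref_resnum 1-based residue number within the reference sequence
#' @return 1-based column index
#' @export
anchor_column <- function(aln, ref_id, ref_resnum) {
  row <- match(ref_id, aln$id)
  if (is.na(row)) stop("reference id not found: ", ref_id)
  ch <- strsplit(aln$seq[row], "", fixed = TRUE)[[1]]
  res_cols <- which(ch != "-")
  if (ref_resnum < 1L || ref_resnum > length(res_cols))
    stop("reference residue number out of range: ", ref_resnum)
  res_cols[ref_resnum]
}

#' Census of cysteines downstream of an anchor column
#'
#' Counts, per record, the cysteines strictly downstream of `anchor_col`
#' (gaps ignored; 'X' is never a cysteine), and summarizes how many records
#' have at least one and at least two.
#'
#' @param aln an [alignment]
#' @param anchor_col 1-based anchor column; counting starts at
#'   `anchor_col + 1`
#' @return object of class `cys_census`: list with `n_total`, `n_ge1`,
#'   `n_ge2` and the per-record `counts` (named by record id)
#' @export
cys_tail_census <- function(aln, anchor_col) {
  nc <- aln_ncol(aln)
  if (!is.numeric(anchor_col) || anchor_col < 1L || anchor_col > nc)
    stop("anchor column out of range")
  tails <- substring(aln$seq, anchor_col + 1L, nc)
  counts <- nchar(tails) - nchar(gsub("C", "", tails, fixed = TRUE))
  res <- structure(list(n_total = nseq(aln),
                        n_ge1 = sum(counts >= 1L),
                        n_ge2 = sum(counts >= 2L),
                        counts = stats::setNames(counts, aln$id)),
                   class = "cys_census")
  stopifnot(res$n_ge2 <= res$n_ge1, res$n_ge1 <= res$n_total)
  res
}

#' @export
print.cys_census <- function(x, ...) {
  cat(sprintf("<cys census: %d sequences; >=1 downstream Cys: %d; >=2: %d>\n",
              x$n_total, x$n_ge1, x$n_ge2))
  invisible(x)
}

#' Write a cysteine census as TSV
#' @param census a [cys_tail_census] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_census_tsv <- function(census, path) {
  df <- data.frame(sequence_id = names(census$counts),
                   n_downstream_cys = unname(census$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
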