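#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-length aligned sequences over the
#' 20-letter amino-acid alphabet plus gap ('-') and unknown ('X'). Any other
#' character (including '.', '*' and lowercase letters outside a3m context)
#' is remapped to 'X'; the number of remapped characters is reported with a
#' message so silent data corruption is visible.
#'
#' @param ids character vector of record identifiers
#' @param seqs character vector of aligned sequences, equal lengths
#' @param source optional per-record provenance tags (e.g. contig ids)
#' @param weights optional per-record weights in (0, 1]
#' @return an object of class `coevo_aln`
#' @export
alignment <- function(ids, seqs, source = NULL, weights = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (length(seqs) == 0L) stop("alignment must contain at least one record")
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L)
    stop("ragged alignment: row lengths ", paste(nc, collapse = ", "))
  if (nc == 0L) stop("alignment must have ncols > 0")
  bad <- gsub(sprintf("[%s-]", paste(c(AA20, "X"), collapse = "")), "", seqs)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0L) {
    message("alignment: remapped ", n_bad, " unknown character(s) to 'X'")
    seqs <- vapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
      ch[!ch %in% ALPHABET] <- "X"
      paste(ch, collapse = "")
    }, character(1))
  }
  if (!is.null(source) && length(source) != length(ids))
    stop("source must have one entry per record")
  if (!is.null(weights)) {
    if (length(weights) != length(ids)) stop("weights must have one entry per record")
    if (any(!is.finite(weights)) || any(weights <= 0) || any(weights > 1))
      stop("weights must lie in (0, 1]")
  }
  structure(list(id = ids, seq = seqs, source = source, weights = weights),
            class = "coevo_aln")
}

#' @export
print.coevo_aln <- function(x, ...) {
  cat(sprintf("<alignment: %d records x %d columns%s>\n", nseq(x), aln_ncol(x),
              if (!is.null(x$weights)) sprintf(", neff = %.2f", sum(x$weights)) else ""))
  show <- utils::head(seq_len(nseq(x)), 5L)
  for (i in show)
    cat(sprintf("  %-20s %s%s\n", substr(x$id[i], 1, 20),
                substr(x$seq[i], 1, 50), if (aln_ncol(x) > 50) "..." else ""))
  if (nseq(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Number of records in an alignment
#' @param aln an [alignment]
#' @export
nseq <- function(aln) length(aln$id)

#' Number of columns in an alignment
#' @param aln an [alignment]
#' @export
aln_ncol <- function(aln) nchar(aln$seq[[1]])

#' Subset alignment rows, preserving order
#' @param aln an [alignment]
#' @param idx integer or logical row index
#' @export
aln_subset <- function(aln, idx) {
  alignment(aln$id[idx], aln$seq[idx],
            source = if (!is.null(aln$source)) aln$source[idx],
            weights = if (!is.null(aln$weights)) aln$weights[idx])
}

#' Subset alignment columns
#' @param aln an [alignment]
#' @param cols integer vector of columns to keep (in order)
#' @export
aln_select_columns <- function(aln, cols) {
  nc <- aln_ncol(aln)
  if (any(cols < 1L | cols > nc)) stop("column index out of range")
  seqs <- vapply(strsplit(aln$seq, "", fixed = TRUE),
                 function(ch) paste(ch[cols], collapse = ""), character(1))
  alignment(aln$id, seqs, source = aln$source, weights = aln$weights)
}

# ---- IO ---------------------------------------------------------------

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "a3m" = "a3m",
         "sto" = "stockholm", "stk" = "stockholm", "stockholm" = "stockholm",
         "fasta")
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, A3M (lowercase insert states are removed to
#' recover the fixed column set) and single- or multi-block Stockholm.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"fasta"`, `"a3m"` or `"stockholm"`
#' @return an [alignment]
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a3m", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         fasta = parse_fasta(lines, path, drop_lower = FALSE),
         a3m = parse_fasta(lines, path, drop_lower = TRUE),
         stockholm = parse_stockholm(lines, path))
}

parse_fasta <- function(lines, path, drop_lower) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L)
    stop("format error in ", path, ": no FASTA header found (line 1)")
  if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1L)]))))
    stop("format error in ", path, ": content before first header (line 1)")
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq.int(hdr[k] + 1L, ends[k])]
    if (hdr[k] + 1L > ends[k]) body <- character(0)
    paste(gsub("\\s", "", body), collapse = "")
  }, character(1))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("format error in ", path, ": empty record at line ", hdr[bad])
  }
  if (drop_lower) {
    seqs <- gsub("[a-z.]", "", seqs) # a3m insert states
    if (length(unique(nchar(seqs))) != 1L)
      stop("consistency error in ", path,
           ": ragged rows after a3m insert removal")
  }
  if (length(unique(nchar(seqs))) != 1L)
    stop("format error in ", path, ": unequal row lengths")
  alignment(ids, seqs)
}

parse_stockholm <- function(lines, path) {
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1]))
    stop("format error in ", path, ": missing '# STOCKHOLM' header (line 1)")
  seqs <- list()
  order <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (ln == "" || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("format error in ", path, ": malformed sequence line ", k)
    id <- parts[1]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
  }
  if (length(seqs) == 0L)
    stop("format error in ", path, ": no sequence lines found")
  s <- unlist(seqs[order], use.names = FALSE)
  s <- gsub("\\.", "-", s)
  alignment(order, s)
}

#' Write an alignment
#'
#' @param aln an [alignment]
#' @param path output file
#' @param format `"fasta"`, `"a3m"` (identical to fasta on fixed-column
#'   alignments) or `"stockholm"`
#' @return `path`, invisibly
#' @export
write_alignment <- function(aln, path, format = c("fasta", "a3m", "stockholm")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "coevo_aln"))
  if (format %in% c("fasta", "a3m")) {
    out <- as.vector(rbind(paste0(">", aln$id), aln$seq))
  } else {
    pad <- max(nchar(aln$id)) + 2L
    out <- c("# STOCKHOLM 1.0",
             sprintf("%-*s%s", pad, aln$id, aln$seq),
             "//")
  }
  writeLines(out, path)
  invisible(path)
}
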