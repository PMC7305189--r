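#' Read gene hits from a GFF3 subset or 6-column TSV
#'
#' The GFF3 dialect uses columns seqid, source, type, start, end, score,
#' strand, phase, attributes; the attributes field must carry `family=` (A
#' or B) and `sequence_id=` (link into a protein alignment; defaults to the
#' `ID=` attribute). The TSV dialect has a header line with columns
#' `contig_id, gene_id, start, end, strand, family` and an optional
#' `sequence_id`.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`
#' @return data.frame of class `gene_hits` with columns `contig_id`,
#'   `gene_id`, `start`, `end`, `strand`, `family`, `sequence_id`
#' @export
read_gene_hits <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene hit file not found: ", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("gff", "gff3")) "gff3" else "tsv"
  if (format == "gff3") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) != 9L)) stop("malformed GFF3 line in ", path)
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
      vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
    }
    attrs <- vapply(f, `[[`, character(1), 9L)
    hits <- data.frame(
      contig_id = vapply(f, `[[`, character(1), 1L),
      gene_id = attr_get(attrs, "ID"),
      start = as.integer(vapply(f, `[[`, character(1), 4L)),
      end = as.integer(vapply(f, `[[`, character(1), 5L)),
      strand = vapply(f, `[[`, character(1), 7L),
      family = attr_get(attrs, "family"),
      sequence_id = attr_get(attrs, "sequence_id"),
      stringsAsFactors = FALSE)
    hits$sequence_id[is.na(hits$sequence_id)] <- hits$gene_id[is.na(hits$sequence_id)]
  } else {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(hits$sequence_id)) hits$sequence_id <- hits$gene_id
  }
  gene_hits(hits)
}

#' Validate a gene-hit table
#' @param hits data.frame with columns `contig_id`, `gene_id`, `start`,
#'   `end`, `strand`, `family` and optionally `sequence_id`
#' @return the validated data.frame, classed `gene_hits`
#' @export
gene_hits <- function(hits) {
  need <- c("contig_id", "gene_id", "start", "end", "strand", "family")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("gene hits missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(hits$contig_id) | !nzchar(hits$contig_id)))
    stop("gene hit lacking contig id")
  if (any(hits$start > hits$end)) stop("gene hit with start > end")
  if (!all(hits$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(hits$family %in% c("A", "B"))) stop("family must be 'A' or 'B'")
  if (is.null(hits$sequence_id)) hits$sequence_id <- hits$gene_id
  rownames(hits) <- NULL
  class(hits) <- c("gene_hits", "data.frame")
  hits
}

#' Write gene hits as GFF3 subset
#' @param hits a [gene_hits] table
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gene_hits <- function(hits, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcoevopair\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%s;sequence_id=%s",
                     hits$contig_id, hits$start, hits$end, hits$strand,
                     hits$gene_id, hits$family, hits$sequence_id))
  writeLines(lines, path)
  invisible(path)
}

# Directional gap from A to B along A's reading direction; negative when B
# is upstream or overlapping.
downstream_gap <- function(a_start, a_end, a_strand, b_start, b_end) {
  ifelse(a_strand == "+", b_start - a_end - 1L, a_start - b_end - 1L)
}

#' Pair family-A and family-B gene hits by contig
#'
#' In `same_contig` mode any A/B hit pair on one contig is a candidate. In
#' `adjacent_downstream` mode the B hit must additionally be on the same
#' strand as A and start downstream of A's 3' end (in A's reading direction)
#' within `max_gap` nucleotides. On contigs with several candidates, pairs
#' are resolved greedily by nearest distance; exact ties are dropped with a
#' warning.
#'
#' @param hits a [gene_hits] table
#' @param mode pairing mode
#' @param max_gap maximum intergenic gap (nt) for `adjacent_downstream`
#' @return data.frame with one row per pair: `contig_id`, `a_gene`,
#'   `b_gene`, `a_seq`, `b_seq`, `distance`
#' @export
find_gene_pairs <- function(hits, mode = c("adjacent_downstream", "same_contig"),
                            max_gap = 500L) {
  mode <- match.arg(mode)
  hits <- gene_hits(as.data.frame(hits))
  out <- list()
  for (ctg in unique(hits$contig_id)) {
    h <- hits[hits$contig_id == ctg, , drop = FALSE]
    A <- h[h$family == "A", , drop = FALSE]
    B <- h[h$family == "B", , drop = FALSE]
    if (nrow(A) == 0L || nrow(B) == 0L) next
    cand <- expand.grid(ai = seq_len(nrow(A)), bi = seq_len(nrow(B)))
    gap <- downstream_gap(A$start[cand$ai], A$end[cand$ai], A$strand[cand$ai],
                          B$start[cand$bi], B$end[cand$bi])
    if (mode == "adjacent_downstream") {
      ok <- A$strand[cand$ai] == B$strand[cand$bi] & gap >= 0L & gap <= max_gap
      cand <- cand[ok, , drop = FALSE]
      cand$dist <- gap[ok]
    } else {
      amid <- (A$start[cand$ai] + A$end[cand$ai]) / 2
      bmid <- (B$start[cand$bi] + B$end[cand$bi]) / 2
      cand$dist <- abs(amid - bmid)
    }
    # greedy nearest-neighbour matching; exact distance ties are dropped
    while (nrow(cand) > 0L) {
      dmin <- min(cand$dist)
      at_min <- which(cand$dist == dmin)
      if (length(at_min) > 1L &&
          (length(unique(cand$ai[at_min])) < length(at_min) ||
           length(unique(cand$bi[at_min])) < length(at_min))) {
        warning("contig ", ctg, ": tied pairing candidates at distance ",
                dmin, " dropped")
        used_a <- unique(cand$ai[at_min])
        used_b <- unique(cand$bi[at_min])
        cand <- cand[!(cand$ai %in% used_a | cand$bi %in% used_b), , drop = FALSE]
        next
      }
      for (k in at_min) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = ctg,
          a_gene = A$gene_id[cand$ai[k]], b_gene = B$gene_id[cand$bi[k]],
          a_seq = A$sequence_id[cand$ai[k]], b_seq = B$sequence_id[cand$bi[k]],
          distance = cand$dist[k], stringsAsFactors = FALSE)
      }
      used_a <- cand$ai[at_min]
      used_b <- cand$bi[at_min]
      cand <- cand[!(cand$ai %in% used_a | cand$bi %in% used_b), , drop = FALSE]
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(0), a_gene = character(0),
                      b_gene = character(0), a_seq = character(0),
                      b_seq = character(0), distance = numeric(0)))
  do.call(rbind, out)
}

#' Build a concatenated paired alignment
#'
#' Row-wise concatenation of the A-region and B-region sequences of each
#' pair; the boundary column (where the B region begins) is recorded.
#' Unpaired rows of either input are excluded.
#'
#' @param alnA,alnB family alignments whose ids are referenced by `pairs`
#' @param pairs data.frame from [find_gene_pairs()] (columns `a_seq`,
#'   `b_seq`), or a two-column data.frame/matrix of (A id, B id)
#' @return object of class `coevo_paired` (also a `coevo_aln`) with fields
#'   `boundary`, `lenA`, `lenB`; ids are joined as `"Aid|Bid"`
#' @export
build_paired_alignment <- function(alnA, alnB, pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!is.null(pairs$a_seq)) {
    aid <- pairs$a_seq; bid <- pairs$b_seq
  } else {
    aid <- pairs[[1]]; bid <- pairs[[2]]
  }
  if (length(aid) == 0L) stop("no pairs: cannot build an empty paired alignment")
  ia <- match(aid, alnA$id)
  ib <- match(bid, alnB$id)
  if (anyNA(ia)) stop("dangling A reference: ", aid[which(is.na(ia))[1]])
  if (anyNA(ib)) stop("dangling B reference: ", bid[which(is.na(ib))[1]])
  paired <- alignment(paste0(alnA$id[ia], "|", alnB$id[ib]),
                      paste0(alnA$seq[ia], alnB$seq[ib]))
  paired$boundary <- aln_ncol(alnA)
  paired$lenA <- aln_ncol(alnA)
  paired$lenB <- aln_ncol(alnB)
  class(paired) <- c("coevo_paired", class(paired))
  paired
}

#' @export
print.coevo_paired <- function(x, ...) {
  cat(sprintf("<paired alignment: %d records, lenA = %d + lenB = %d = %d columns>\n",
              nseq(x), x$lenA, x$lenB, aln_ncol(x)))
  invisible(x)
}

#' Trim terminal regions of a paired alignment
#'
#' Removes leading/trailing columns of the A and B regions — by explicit
#' counts (defaults: the first 9 columns of A and the last 10 of B), or,
#' when `contact_support` is supplied, by trimming the maximal terminal runs
#' of unsupported columns in each region. Only terminal trimming is
#' supported; the boundary is updated.
#'
#' @param paired a [build_paired_alignment()] result
#' @param a_head,a_tail,b_head,b_tail numbers of columns to drop at each
#'   region terminus
#' @param contact_support optional logical per-column flag (TRUE = column is
#'   supported by predicted contacts); overrides the explicit counts
#' @return trimmed `coevo_paired`
#' @export
trim_termini <- function(paired, a_head = 9L, a_tail = 0L, b_head = 0L,
                         b_tail = 10L, contact_support = NULL) {
  stopifnot(inherits(paired, "coevo_paired"))
  lenA <- paired$lenA; lenB <- paired$lenB
  if (!is.null(contact_support)) {
    if (length(contact_support) != lenA + lenB)
      stop("contact_support must have one flag per column")
    run_head <- function(x) { r <- rle(x); if (!r$values[1]) r$lengths[1] else 0L }
    supA <- contact_support[seq_len(lenA)]
    supB <- contact_support[lenA + seq_len(lenB)]
    a_head <- run_head(supA); a_tail <- run_head(rev(supA))
    b_head <- run_head(supB); b_tail <- run_head(rev(supB))
  }
  for (v in c(a_head, a_tail, b_head, b_tail))
    if (v < 0L) stop("trim counts must be non-negative")
  if (a_head + a_tail >= lenA) stop("trim range covers the whole A region")
  if (b_head + b_tail >= lenB) stop("trim range covers the whole B region")
  keepA <- seq.int(a_head + 1L, lenA - a_tail)
  keepB <- lenA + seq.int(b_head + 1L, lenB - b_tail)
  out <- aln_select_columns(paired, c(keepA, keepB))
  out$lenA <- length(keepA)
  out$lenB <- length(keepB)
  out$boundary <- out$lenA
  class(out) <- c("coevo_paired", class(out))
  out
}
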