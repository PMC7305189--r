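#' Construct a structure-coordinates table
#'
#' @param chain,resno,resname,atom,x,y,z equal-length vectors of atom records
#' @param het logical HETATM flag (default FALSE)
#' @return data.frame of class `structure_coords`
#' @export
structure_coords <- function(chain, resno, resname, atom, x, y, z, het = FALSE) {
  df <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                   resname = as.character(resname), atom = as.character(atom),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   het = rep_len(as.logical(het), length(chain)),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates")
  class(df) <- c("structure_coords", "data.frame")
  df
}

#' Read a PDB file (ATOM/HETATM records)
#'
#' Minimal fixed-column PDB reader: serial, atom name, altLoc, residue
#' name, chain, residue number, x/y/z. Alternate locations other than ' '
#' or 'A' are dropped. mmCIF is not supported.
#'
#' @param path PDB file
#' @return a [structure_coords] data.frame
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  altloc <- substr(lines, 17, 17)
  lines <- lines[altloc %in% c(" ", "A")]
  structure_coords(
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    atom = trimws(substr(lines, 13, 16)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    het = substr(lines, 1, 6) == "HETATM")
}

#' Write coordinates as PDB text
#' @param coords a [structure_coords] data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(coords, path) {
  rec <- ifelse(coords$het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(coords$atom) < 4L, sprintf(" %-3s", coords$atom),
                 coords$atom)
  lines <- sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   rec, seq_len(nrow(coords)), name, coords$resname,
                   coords$chain, coords$resno, coords$x, coords$y, coords$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Per-residue representative points (Cbeta, Calpha for glycine)
#'
#' Residues lacking a representative atom are skipped with a warning.
#'
#' @param coords a [structure_coords] data.frame
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, `x`, `y`, `z`, ordered by chain appearance then residue
#'   number
#' @export
representative_points <- function(coords) {
  prot <- coords[!coords$het, , drop = FALSE]
  key <- paste(prot$chain, prot$resno)
  res_keys <- unique(key)
  rows <- lapply(res_keys, function(k) {
    at <- prot[key == k, , drop = FALSE]
    want <- if (at$resname[1] == "GLY") "CA" else "CB"
    hit <- which(at$atom == want)
    if (length(hit) == 0L && want == "CB") hit <- which(at$atom == "CA")
    if (length(hit) == 0L) {
      warning("residue ", k, " lacks a representative atom; skipped")
      return(NULL)
    }
    at[hit[1], c("chain", "resno", "resname", "x", "y", "z"), drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2L)
    stop("fewer than two residues with representative atoms")
  chains <- unique(out$chain)
  out <- out[order(match(out$chain, chains), out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a contact map
#' @param npos number of positions
#' @param pairs 2-column matrix of position pairs (i < j enforced)
#' @param cutoff,min_sep map conventions (stored for provenance)
#' @param chain optional chain label per position
#' @param resno optional residue number per position
#' @return object of class `contact_map`
#' @export
contact_map <- function(npos, pairs, cutoff = 8, min_sep = 6L, chain = NULL,
                        resno = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0L) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs < 1L | pairs > npos)) stop("contact pair out of range")
    if (any(pairs[, 1] == pairs[, 2])) stop("self-contact not allowed")
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(list(npos = npos, pairs = pairs, cutoff = cutoff,
                 min_sep = min_sep, chain = chain, resno = resno),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact map: %d positions, %d contacts (cutoff %.1f A, min_sep %d)>\n",
              x$npos, nrow(x$pairs), x$cutoff, x$min_sep))
  invisible(x)
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Observed contact map from structure coordinates
#'
#' A pair of residues is a contact iff their representative points (Cbeta,
#' Calpha for glycine) are closer than `cutoff` and their within-chain
#' separation is at least `min_sep`; cross-chain pairs are exempt from the
#' separation rule. Positions are numbered sequentially across chains in
#' order of appearance.
#'
#' @param coords a [structure_coords] data.frame
#' @param cutoff distance cutoff in Angstrom (default 8)
#' @param min_sep minimum within-chain separation (default 6)
#' @return a [contact_map]
#' @export
contact_map_from_structure <- function(coords, cutoff = 8, min_sep = 6L) {
  rep <- representative_points(coords)
  n <- nrow(rep)
  xyz <- as.matrix(rep[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(rep$chain, rep$chain, "==")
  # separation in residue numbering, so structures with missing residues
  # keep their true sequence distances
  sep <- abs(outer(rep$resno, rep$resno, "-"))
  ok <- d < cutoff & (!same_chain | sep >= min_sep) & upper.tri(d)
  idx <- which(ok, arr.ind = TRUE)
  contact_map(n, idx, cutoff = cutoff, min_sep = min_sep,
              chain = rep$chain, resno = rep$resno)
}

#' Precision of the top-k contact predictions
#'
#' @param preds a `contact_pred` data.frame (re-sorted by probability)
#' @param observed a [contact_map]
#' @param k number of top predictions to evaluate; if larger than the
#'   prediction list, all predictions are used and the result carries
#'   attribute `truncated = TRUE`
#' @return fraction of the top-k predictions present in `observed`
#' @export
precision_at <- function(preds, observed, k) {
  if (k < 1L) stop("k must be >= 1")
  preds <- preds[order(-preds$prob), , drop = FALSE]
  truncated <- k > nrow(preds)
  if (truncated) {
    warning("k = ", k, " exceeds available predictions (", nrow(preds),
            "); evaluating on all")
    k <- nrow(preds)
  }
  top <- preds[seq_len(k), , drop = FALSE]
  obs <- pair_key(observed$pairs[, 1], observed$pairs[, 2])
  p <- mean(pair_key(top$i, top$j) %in% obs)
  if (truncated) attr(p, "truncated") <- TRUE
  p
}

#' Interdomain contact extraction
#'
#' @param preds a `contact_pred` data.frame
#' @param boundaries named list of inclusive index ranges, e.g.
#'   `list(CBD = c(1, 160), TMD = c(161, 290), B = c(291, 419))`; ranges
#'   must partition the position range without overlap
#' @param threshold minimum probability
#' @return subset of `preds` whose endpoints fall in different regions,
#'   with added columns `region_i`, `region_j`, `region_pair`
#' @export
interdomain_contacts <- function(preds, boundaries, threshold = 0.5) {
  rng <- do.call(rbind, boundaries)
  if (any(rng[, 1] > rng[, 2])) stop("malformed region range")
  ord <- order(rng[, 1])
  rng <- rng[ord, , drop = FALSE]
  if (nrow(rng) > 1L && any(rng[-1, 1] <= rng[-nrow(rng), 2]))
    stop("overlapping regions")
  region_of <- function(pos) {
    r <- names(boundaries)[vapply(boundaries, function(b)
      any(pos >= b[1] & pos <= b[2]), logical(1))]
    if (length(r) == 0L) NA_character_ else r
  }
  region_i <- vapply(preds$i, region_of, character(1))
  region_j <- vapply(preds$j, region_of, character(1))
  keep <- !is.na(region_i) & !is.na(region_j) & region_i != region_j &
    preds$prob >= threshold
  out <- as.data.frame(preds)[keep, , drop = FALSE]
  out$region_i <- region_i[keep]
  out$region_j <- region_j[keep]
  out$region_pair <- paste(out$region_i, out$region_j, sep = "-")
  rownames(out) <- NULL
  out
}

#' Model-fit ratio Rc
#'
#' Rc = (number of the top-n predictions satisfied in the model contact
#' map) / (sum of the predicted probabilities over the same top-n). Values
#' for native structures typically fall in 0.7-1.2 (attached as attribute
#' `native_band`).
#'
#' @param preds a `contact_pred` data.frame
#' @param model_map [contact_map] of the structural model
#' @param top_n number of top predictions to assess
#' @return Rc, with attribute `native_band = c(0.7, 1.2)`
#' @export
model_fit_rc <- function(preds, model_map, top_n) {
  preds <- preds[order(-preds$prob), , drop = FALSE]
  if (top_n > nrow(preds)) stop("top_n exceeds available predictions")
  top <- preds[seq_len(top_n), , drop = FALSE]
  denom <- sum(top$prob)
  if (denom <= 0) stop("zero probability mass in the top predictions")
  obs <- pair_key(model_map$pairs[, 1], model_map$pairs[, 2])
  satisfied <- sum(pair_key(top$i, top$j) %in% obs)
  structure(satisfied / denom, native_band = c(0.7, 1.2))
}

# ---- atom selection & geometry ---------------------------------------

#' Select atoms with "chain:resno:atom" glob patterns
#'
#' Each component supports shell globs, e.g. `"B:*:FE*"` selects all iron
#' atoms on chain B.
#'
#' @param coords a [structure_coords] data.frame
#' @param selector selector string
#' @return subset of `coords`
#' @export
select_atoms <- function(coords, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("selector must be 'chain:resno:atom': ", selector)
  ok <- grepl(utils::glob2rx(parts[1]), coords$chain) &
    grepl(utils::glob2rx(parts[2]), as.character(coords$resno)) &
    grepl(utils::glob2rx(parts[3]), coords$atom)
  coords[ok, , drop = FALSE]
}

#' Minimum distance between two atom selections
#'
#' @param coords a [structure_coords] data.frame
#' @param group_a,group_b atom selectors (see [select_atoms()])
#' @return minimum pairwise distance in Angstrom
#' @export
cofactor_distance <- function(coords, group_a, group_b) {
  A <- select_atoms(coords, group_a)
  B <- select_atoms(coords, group_b)
  if (nrow(A) == 0L) stop("empty selection: ", group_a)
  if (nrow(B) == 0L) stop("empty selection: ", group_b)
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation R and translation t minimizing
#' `||mobile %*% R + t - target||` (row-vector convention).
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, matched rows
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length
#'   3), `rmsd`, and `degenerate` (TRUE when the point set is rank-deficient,
#'   e.g. collinear; a valid solution is still returned)
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("point sets must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  Pm <- sweep(mobile, 2, cm); Pt <- sweep(target, 2, ct)
  H <- crossprod(Pm, Pt)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  if (degenerate) warning("degenerate (collinear) point set in superposition")
  t_vec <- ct - as.vector(cm %*% R)
  fitted <- sweep(mobile %*% R, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, degenerate = degenerate)
}

#' Template contact coverage / template-gap score
#'
#' Fraction of the top-L predicted contacts whose endpoints both map onto
#' the template and form a contact there; the complement (1 - coverage) is
#' reported as the template-gap score. A simplified stand-in for
#' HMM-profile template assessment.
#'
#' @param preds a `contact_pred` data.frame (nonempty)
#' @param template_map [contact_map] of the template
#' @param mapping integer vector: `mapping[q]` is the template position of
#'   query position q, NA where unmapped
#' @return list with `coverage`, `gap_score`, `n_top`
#' @export
template_coverage <- function(preds, template_map, mapping) {
  if (nrow(preds) == 0L) stop("empty prediction list")
  if (length(mapping) == 0L || all(is.na(mapping))) stop("empty mapping")
  L <- length(mapping)
  preds <- preds[order(-preds$prob), , drop = FALSE]
  top <- preds[seq_len(min(L, nrow(preds))), , drop = FALSE]
  ti <- mapping[top$i]; tj <- mapping[top$j]
  obs <- pair_key(template_map$pairs[, 1], template_map$pairs[, 2])
  hit <- !is.na(ti) & !is.na(tj) & pair_key(ti, tj) %in% obs
  list(coverage = mean(hit), gap_score = 1 - mean(hit), n_top = nrow(top))
}

# ---- contact map IO ---------------------------------------------------

#' Write a contact map as TSV
#' @param cmap a [contact_map]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_contact_map <- function(cmap, path) {
  hdr <- sprintf("# npos=%d cutoff=%g min_sep=%d", cmap$npos, cmap$cutoff,
                 cmap$min_sep)
  body <- if (nrow(cmap$pairs)) sprintf("%d\t%d", cmap$pairs[, 1], cmap$pairs[, 2])
          else character(0)
  writeLines(c(hdr, "i\tj", body), path)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#' @param path input file
#' @return a [contact_map]
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  get <- function(key) as.numeric(sub(paste0(".*", key, "="), "",
                                      regmatches(hdr, regexpr(paste0(key, "=[0-9.]+"), hdr))))
  body <- lines[-(1:2)]
  pairs <- if (length(body))
    matrix(as.integer(unlist(strsplit(body, "\t"))), ncol = 2, byrow = TRUE)
  else matrix(integer(0), ncol = 2)
  contact_map(get("npos"), pairs, cutoff = get("cutoff"),
              min_sep = as.integer(get("min_sep")))
}
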