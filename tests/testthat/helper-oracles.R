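# Independent oracles used across tests. These deliberately re-derive
# quantities with naive pure-R code so they never share a code path with
# the implementation under test.

# identity: matches over mutually non-gap columns / columns occupied in
# either sequence; 'X' never matches
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  occ <- ca != "-" | cb != "-"
  hit <- ca == cb & ca != "-" & ca != "X"
  if (sum(occ) == 0) 0 else sum(hit & occ) / sum(occ)
}

# greedy first-seen-wins filter via exhaustive pairwise identities
oracle_greedy_filter <- function(seqs, max_id) {
  kept <- integer(0)
  for (s in seq_along(seqs)) {
    if (all(vapply(kept, function(k)
      oracle_identity(seqs[s], seqs[k]) <= max_id, logical(1))))
      kept <- c(kept, s)
  }
  kept
}

oracle_weights <- function(seqs, thr) {
  n <- length(seqs)
  counts <- vapply(seq_len(n), function(s)
    sum(vapply(seq_len(n), function(t)
      oracle_identity(seqs[s], seqs[t]) >= thr, logical(1))), numeric(1))
  1 / counts
}

# all-pairs contact scan on a representative-point table (separation in
# residue numbering, matching the implementation's convention)
oracle_contacts <- function(rep_pts, cutoff, min_sep) {
  n <- nrow(rep_pts)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((as.numeric(rep_pts[i, c("x", "y", "z")]) -
                     as.numeric(rep_pts[j, c("x", "y", "z")]))^2))
    same <- rep_pts$chain[i] == rep_pts$chain[j]
    if (d < cutoff &&
        (!same || abs(rep_pts$resno[j] - rep_pts$resno[i]) >= min_sep))
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

random_aln <- function(n, L, gap_frac = 0.1) {
  chars <- c(coevopair:::AA20, "-")
  probs <- c(rep((1 - gap_frac) / 20, 20), gap_frac)
  seqs <- replicate(n, paste(sample(chars, L, TRUE, probs), collapse = ""))
  alignment(sprintf("r%03d", seq_len(n)), seqs)
}

random_rot <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# tiny deterministic helix-like trace for structure tests
helix_coords <- function(n, chain = "A") {
  t <- seq_len(n)
  structure_coords(chain = chain, resno = t, resname = "ALA", atom = "CB",
                   x = 2.3 * cos(t * 100 * pi / 180),
                   y = 2.3 * sin(t * 100 * pi / 180),
                   z = 1.5 * t)
}
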