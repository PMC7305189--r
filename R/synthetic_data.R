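# Run code under a local RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators are deterministic per seed
# without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Compact self-avoiding chain: consecutive points 3.8 A apart, no two
# points closer than `clash`, with a centroid-seeking bias that yields
# globular folds (protein-like contact density at the 8 A convention).
compact_walk <- function(n, spacing = 3.8, clash = 3.6, bias = 0.6,
                         max_restart = 200L) {
  for (attempt in seq_len(max_restart)) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      ctr <- colMeans(pts[seq_len(k - 1L), , drop = FALSE])
      for (try in 1:60) {
        dir <- rnorm(3)
        pull <- ctr - pts[k - 1L, ]
        pn <- sqrt(sum(pull^2))
        if (pn > 1e-8) dir <- dir + bias * pull / pn * sqrt(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- pts[k - 1L, ] + spacing * dir
        if (k > 2L) {
          d2 <- rowSums(sweep(pts[seq_len(k - 2L), , drop = FALSE], 2, cand)^2)
          if (min(d2) < clash^2) next
        }
        pts[k, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("failed to generate a self-avoiding chain after ", max_restart,
       " restarts")
}

toy_structure_coords <- function(coordsA, coordsB) {
  structure_coords(
    chain = c(rep("A", nrow(coordsA)), rep("B", nrow(coordsB))),
    resno = c(seq_len(nrow(coordsA)), seq_len(nrow(coordsB))),
    resname = "ALA", atom = "CB",
    x = c(coordsA[, 1], coordsB[, 1]),
    y = c(coordsA[, 2], coordsB[, 2]),
    z = c(coordsA[, 3], coordsB[, 3]))
}

#' Generate a toy two-chain complex with known contacts
#'
#' Each chain is a compact self-avoiding pseudo-Calpha trace (3.8 Angstrom
#' spacing); chain B is rotated randomly and slid toward chain A until at
#' least `min_interchain` cross-chain contacts form (without steric
#' clashes). The ground-truth contact map is derived from the coordinates
#' with the package's own convention ([contact_map_from_structure()]).
#'
#' @param lenA,lenB chain lengths (>= 10)
#' @param seed integer seed; same seed, same complex
#' @param cutoff,min_sep contact-map convention
#' @param min_interchain minimum number of cross-chain contacts (default 3)
#' @param max_tries placement attempts before giving up
#' @return object of class `toy_complex`: `coordsA`, `coordsB`, `coords`
#'   (a [structure_coords]), `true_contacts` (a [contact_map]), `lenA`,
#'   `lenB`, `seed`
#' @export
make_toy_complex <- function(lenA, lenB, seed, cutoff = 8, min_sep = 6L,
                             min_interchain = 3L, max_tries = 50L) {
  if (lenA < 10L || lenB < 10L) stop("chain lengths must be >= 10")
  with_seed(seed, {
    A <- compact_walk(lenA)
    A <- sweep(A, 2, colMeans(A))
    for (try in seq_len(max_tries)) {
      B0 <- compact_walk(lenB)
      B0 <- sweep(B0, 2, colMeans(B0)) %*% random_rotation()
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      radA <- max(sqrt(rowSums(A^2)))
      radB <- max(sqrt(rowSums(B0^2)))
      placed <- NULL
      for (d in seq(radA + radB + 8, 2, by = -0.5)) {
        B <- sweep(B0, 2, d * u, "+")
        dmat <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") -
                            2 * A %*% t(B), 0))
        if (min(dmat) < 3.6) break # clash: stop approaching
        if (sum(dmat < cutoff) >= min_interchain) { placed <- B; break }
      }
      if (!is.null(placed)) {
        coords <- toy_structure_coords(A, placed)
        return(structure(list(
          coordsA = A, coordsB = placed, coords = coords,
          true_contacts = contact_map_from_structure(coords, cutoff, min_sep),
          lenA = lenA, lenB = lenB, seed = seed),
          class = "toy_complex"))
      }
    }
    stop("failed to place chain B with >= ", min_interchain,
         " interchain contacts after ", max_tries, " tries")
  })
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy complex: lenA = %d, lenB = %d, %d true contacts (seed %d)>\n",
              x$lenA, x$lenB, nrow(x$true_contacts$pairs), x$seed))
  invisible(x)
}

#' Planted Potts model from a contact map
#'
#' Fields are drawn from a random per-column profile (gap state strongly
#' disfavored). Each contact pair receives a "lock-and-key" coupling block:
#' a random bijection sigma of the 20 amino acids with
#' `J[a, sigma(a)] = coupling_strength`, which makes contacting columns
#' strongly correlated while non-contact pairs stay independent.
#'
#' @param cmap a [contact_map] defining where couplings live
#' @param coupling_strength coupling magnitude (0 = independent columns)
#' @param seed integer seed
#' @param field_sd standard deviation of the amino-acid field profile
#' @return a `potts_model` (same layout as [fit_potts()] output); the
#'   planted contact map is attached as attribute `planted`
#' @export
potts_from_contacts <- function(cmap, coupling_strength = 1.0, seed,
                                field_sd = 0.5) {
  L <- cmap$npos
  q <- 21L
  with_seed(seed, {
    fields <- cbind(matrix(rnorm(L * 20L, 0, field_sd), L, 20L),
                    rep(-6, L)) # gap state rare
    P <- L * (L - 1L) / 2L
    J <- numeric(P * q * q)
    if (coupling_strength != 0 && nrow(cmap$pairs) > 0L) {
      for (k in seq_len(nrow(cmap$pairs))) {
        i <- cmap$pairs[k, 1]; j <- cmap$pairs[k, 2]
        p <- (i - 1) * L - (i - 1) * i / 2 + (j - i - 1) # 0-based pair index
        sigma <- sample.int(20L)
        idx <- (p * q * q) + (sigma - 1L) * q + seq_len(20L)
        J[idx] <- coupling_strength
      }
    }
    structure(list(fields = fields, couplings = J, ncols = L, q = q,
                   lambda_field = NA_real_, lambda_coupling = NA_real_,
                   neff = NA_real_, objective = NA_real_, trace = NULL),
              class = "potts_model", planted = cmap)
  })
}

#' Sample an alignment from a Potts model by Gibbs sampling
#'
#' Single-chain site-wise Gibbs sampling over the 21-state alphabet;
#' `thin` full sweeps separate emitted rows after `burn_in` sweeps.
#' Deterministic per seed.
#'
#' @param model a `potts_model`
#' @param n number of sequences to emit
#' @param burn_in,thin sweeps before the first sample / between samples
#' @param seed integer seed
#' @return an [alignment] with records `seq00001`, ...
#' @export
sample_sequences <- function(model, n, burn_in = 500L, thin = 10L, seed) {
  if (n < 1L) stop("n must be >= 1")
  par <- c(as.vector(t(model$fields)), model$couplings)
  codes <- with_seed(seed,
    gibbs_sample_cpp(par, model$ncols, as.integer(n), as.integer(burn_in),
                     as.integer(thin)))
  alignment(sprintf("seq%05d", seq_len(n)), decode_rows(codes + 1L))
}

#' Synthetic metagenome contigs with planted adjacent gene pairs
#'
#' Every planted pair places a family-A gene with its family-B partner
#' immediately downstream on the same strand (intergenic gap 20..`max_gap`
#' nt). Decoy contigs cycle through three types: a lone A gene, a lone B
#' gene, and an A gene with a B gene downstream on the opposite strand.
#' Protein sequences for the genes are taken row-by-row from `alnA`/`alnB`
#' when supplied (e.g. Potts-sampled families), otherwise drawn uniformly
#' from the 20-letter alphabet.
#'
#' @param n_pairs number of planted A+B pairs
#' @param n_decoys number of decoy contigs
#' @param seed integer seed
#' @param alnA,alnB optional [alignment]s supplying protein sequences
#'   (gaps are stripped for gene lengths); rows are consumed in order —
#'   pairs first, then decoys
#' @param max_gap maximum planted intergenic gap (nt), default 200
#' @param lenA,lenB protein lengths when no alignments are given
#' @return list with `hits` (a [gene_hits] table), `contig_len` (named
#'   integer vector), `proteins` (list of two [alignment]s or NULL),
#'   `truth` (data.frame of planted pairs: `contig_id`, `a_seq`, `b_seq`)
#' @export
make_contigs <- function(n_pairs, n_decoys = 0L, seed, alnA = NULL,
                         alnB = NULL, max_gap = 200L, lenA = 30L, lenB = 20L) {
  if (n_pairs < 0L || n_decoys < 0L) stop("counts must be >= 0")
  rand_prot <- function(len) paste(sample(AA20, len, replace = TRUE),
                                   collapse = "")
  with_seed(seed, {
    needA <- n_pairs + ceiling(n_decoys * 2 / 3) + 1L
    needB <- n_pairs + n_decoys + 1L
    seqA <- if (!is.null(alnA)) {
      if (nseq(alnA) < needA) stop("alnA has too few rows")
      stats::setNames(gsub("-", "", alnA$seq, fixed = TRUE), alnA$id)
    } else stats::setNames(replicate(needA, rand_prot(lenA)),
                           sprintf("protA%04d", seq_len(needA)))
    seqB <- if (!is.null(alnB)) {
      if (nseq(alnB) < needB) stop("alnB has too few rows")
      stats::setNames(gsub("-", "", alnB$seq, fixed = TRUE), alnB$id)
    } else stats::setNames(replicate(needB, rand_prot(lenB)),
                           sprintf("protB%04d", seq_len(needB)))
    ai <- 0L; bi <- 0L
    nextA <- function() { ai <<- ai + 1L; seqA[ai] }
    nextB <- function() { bi <<- bi + 1L; seqB[bi] }

    hits <- list(); clens <- integer(0); truth <- list()
    add_contig <- function(id, genes, clen) {
      clens[[id]] <<- clen
      for (g in genes) hits[[length(hits) + 1L]] <<- data.frame(
        contig_id = id, gene_id = g$gene_id, start = g$start, end = g$end,
        strand = g$strand, family = g$family, sequence_id = g$sequence_id,
        stringsAsFactors = FALSE)
    }
    lay_pair <- function(id, sA, sB, same_strand) {
      la <- 3L * nchar(sA); lb <- 3L * nchar(sB)
      flank <- sample(50:300, 1L)
      gap <- sample(20:max_gap, 1L)
      a <- c(flank + 1L, flank + la)
      b <- c(a[2] + gap + 1L, a[2] + gap + lb)
      clen <- b[2] + sample(50:300, 1L)
      strand <- sample(c("+", "-"), 1L)
      flip <- function(iv) c(clen - iv[2] + 1L, clen - iv[1] + 1L)
      if (strand == "-") { a <- flip(a); b <- flip(b) }
      b_strand <- if (same_strand) strand else setdiff(c("+", "-"), strand)
      list(clen = clen,
           A = list(gene_id = paste0(id, "_gA"), start = a[1], end = a[2],
                    strand = strand, family = "A",
                    sequence_id = names(sA)),
           B = list(gene_id = paste0(id, "_gB"), start = b[1], end = b[2],
                    strand = b_strand, family = "B",
                    sequence_id = names(sB)))
    }

    if (n_pairs > 0L) for (k in seq_len(n_pairs)) {
      id <- sprintf("ctg%04d", k)
      sA <- nextA(); sB <- nextB()
      lp <- lay_pair(id, sA, sB, same_strand = TRUE)
      add_contig(id, list(lp$A, lp$B), lp$clen)
      truth[[k]] <- data.frame(contig_id = id, a_seq = names(sA),
                               b_seq = names(sB), stringsAsFactors = FALSE)
    }
    if (n_decoys > 0L) for (k in seq_len(n_decoys)) {
      id <- sprintf("decoy%04d", k)
      type <- c("lone_A", "lone_B", "antisense_B")[(k - 1L) %% 3L + 1L]
      if (type == "lone_A") {
        sA <- nextA(); la <- 3L * nchar(sA)
        st <- sample(50:300, 1L)
        add_contig(id, list(list(gene_id = paste0(id, "_gA"), start = st,
                                 end = st + la - 1L,
                                 strand = sample(c("+", "-"), 1L),
                                 family = "A", sequence_id = names(sA))),
                   st + la + sample(50:300, 1L))
      } else if (type == "lone_B") {
        sB <- nextB(); lb <- 3L * nchar(sB)
        st <- sample(50:300, 1L)
        add_contig(id, list(list(gene_id = paste0(id, "_gB"), start = st,
                                 end = st + lb - 1L,
                                 strand = sample(c("+", "-"), 1L),
                                 family = "B", sequence_id = names(sB))),
                   st + lb + sample(50:300, 1L))
      } else {
        sA <- nextA(); sB <- nextB()
        lp <- lay_pair(id, sA, sB, same_strand = FALSE)
        add_contig(id, list(lp$A, lp$B), lp$clen)
      }
    }
    hits_df <- if (length(hits)) gene_hits(do.call(rbind, hits))
               else gene_hits(data.frame(contig_id = character(0),
                                         gene_id = character(0),
                                         start = integer(0), end = integer(0),
                                         strand = character(0),
                                         family = character(0),
                                         sequence_id = character(0)))
    list(hits = hits_df, contig_len = clens,
         proteins = list(A = alnA, B = alnB),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(contig_id = character(0),
                                 a_seq = character(0), b_seq = character(0)))
  })
}

# ---- synthetic reference ferredoxin ----------------------------------

# NeRF internal-coordinate placement: returns p4 with |p4-p3| = bond,
# angle(p4,p3,p2) = angle_deg and dihedral(p1,p2,p3,p4) = dihedral_deg.
place_internal <- function(p1, p2, p3, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  ph <- -dihedral_deg * pi / 180 # sign matches dihedral_deg()'s convention
  b1 <- p2 - p1
  b2 <- p3 - p2
  nb2 <- b2 / vnorm(b2)
  n <- cross3(b1, b2); n <- n / vnorm(n)
  m <- cross3(n, nb2)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  p3 + d[1] * nb2 + d[2] * m + d[3] * n
}

#' Synthetic idealized dicluster ferredoxin (reference stand-in)
#'
#' Deterministically constructs a SYNTHETIC stand-in for a high-resolution
#' dicluster ferredoxin: two ideal 4Fe-4S cubane clusters (Fe-Fe 2.65
#' Angstrom, Fe-Sgamma 2.28 Angstrom, mid-range crystallographic values)
#' each ligated by four cysteines whose Calpha-Cbeta-Sgamma angles and
#' C-Calpha-Cbeta-Sgamma dihedrals are built at the published per-motif
#' restraint values. This is NOT an experimental structure; it exists so
#' that geometry extraction can be exercised offline. Cysteine residue
#' numbers follow the conventional dicluster-ferredoxin motif numbering
#' (cluster I: 8, 11, 14, 47; cluster II: 18, 35, 38, 41; chain A);
#' cluster Fe/S atoms are emitted as HETATM residues SF4 101 and 102.
#'
#' @param spec geometry targets, default [cluster_geometry_defaults()]
#' @return a [structure_coords] data.frame
#' @export
synthetic_ferredoxin <- function(spec = cluster_geometry_defaults()) {
  fe_fe <- 2.65
  fe_sg <- 2.28
  r_fe <- fe_fe * sqrt(3 / 8)  # circumradius of the Fe tetrahedron
  r_sg <- r_fe + fe_sg
  r_s <- 2.26                  # inorganic sulfide radius (Fe-S ~2.3)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  build_cluster <- function(center, rot, resnos, sf4_resno) {
    U <- tet %*% rot
    fe <- sweep(U * r_fe, 2, center, "+")
    ss <- sweep(-U * r_s, 2, center, "+")
    rows <- list()
    for (k in 1:4) {
      u <- U[k, ]
      # arbitrary stable perpendicular
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v <- cross3(u, ref); v <- v / vnorm(v)
      sg <- center + r_sg * u
      cb <- sg + 1.81 * u
      th <- spec$angles[k] * pi / 180
      ca <- cb + 1.53 * (-cos(th) * u + sin(th) * v)
      cc <- place_internal(sg, cb, ca, 1.52, 111, spec$dihedrals[k])
      rows[[k]] <- data.frame(
        chain = "A", resno = resnos[k], resname = "CYS",
        atom = c("C", "CA", "CB", "SG"),
        x = c(cc[1], ca[1], cb[1], sg[1]),
        y = c(cc[2], ca[2], cb[2], sg[2]),
        z = c(cc[3], ca[3], cb[3], sg[3]),
        het = FALSE, stringsAsFactors = FALSE)
    }
    rows[[5]] <- data.frame(
      chain = "A", resno = sf4_resno, resname = "SF4",
      atom = c(paste0("FE", 1:4), paste0("S", 1:4)),
      x = c(fe[, 1], ss[, 1]), y = c(fe[, 2], ss[, 2]),
      z = c(fe[, 3], ss[, 3]), het = TRUE, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }
  rot2 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3) # fixed axis permutation
  df <- rbind(
    build_cluster(c(0, 0, 0), diag(3), c(8L, 11L, 14L, 47L), 101L),
    build_cluster(c(12, 0, 0), rot2, c(18L, 35L, 38L, 41L), 102L))
  structure_coords(df$chain, df$resno, df$resname, df$atom, df$x, df$y,
                   df$z, df$het)
}
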