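RESTRAINT_KINDS <- c("harmonic_distance", "bounded_distance",
                     "sigmoidal_distance", "harmonic_angle",
                     "circular_harmonic_dihedral")
ATOMS_PER_KIND <- c(harmonic_distance = 2L, bounded_distance = 2L,
                    sigmoidal_distance = 2L, harmonic_angle = 3L,
                    circular_harmonic_dihedral = 4L)

#' Construct a restraint set
#'
#' A restraint binds 2-4 atom selectors (`"chain:resno:atom"`) to a penalty
#' function. Parameter meaning by kind: `harmonic_distance` center/width
#' (Angstrom); `bounded_distance` lower/upper/width (Angstrom);
#' `sigmoidal_distance` anchor/slope; `harmonic_angle` and
#' `circular_harmonic_dihedral` center/width (degrees).
#'
#' @param kind character vector of restraint kinds
#' @param atoms list of character vectors of atom selectors (2-4 each)
#' @param p1,p2,p3 numeric parameters (`p3` only for bounded)
#' @param stage_tag `"all_stages"` or `"centroid_only"`
#' @return data.frame of class `restraint_set` with columns `kind`,
#'   `a1`..`a4`, `p1`..`p3`, `stage_tag`
#' @export
restraint_set <- function(kind, atoms, p1, p2, p3 = NA_real_,
                          stage_tag = "all_stages") {
  n <- length(kind)
  if (!all(kind %in% RESTRAINT_KINDS))
    stop("unknown restraint kind: ", paste(setdiff(kind, RESTRAINT_KINDS), collapse = ", "))
  if (length(atoms) != n) stop("one atom vector per restraint required")
  na <- lengths(atoms)
  if (any(na != ATOMS_PER_KIND[kind]))
    stop("atom count does not match restraint kind")
  stage_tag <- rep_len(stage_tag, n)
  if (!all(stage_tag %in% c("all_stages", "centroid_only")))
    stop("stage_tag must be 'all_stages' or 'centroid_only'")
  p1 <- rep_len(as.numeric(p1), n); p2 <- rep_len(as.numeric(p2), n)
  p3 <- rep_len(as.numeric(p3), n)
  width <- ifelse(kind == "bounded_distance", p3, p2)
  if (any(!is.finite(width) | width <= 0))
    stop("restraint widths must be positive")
  if (any(kind == "bounded_distance" & p1 >= p2))
    stop("bounded restraint requires lower < upper")
  amat <- t(vapply(atoms, function(a) c(a, rep(NA_character_, 4L - length(a))),
                   character(4)))
  df <- data.frame(kind = kind, a1 = amat[, 1], a2 = amat[, 2],
                   a3 = amat[, 3], a4 = amat[, 4],
                   p1 = p1, p2 = p2, p3 = p3, stage_tag = stage_tag,
                   stringsAsFactors = FALSE)
  class(df) <- c("restraint_set", "data.frame")
  df
}

#' Concatenate restraint sets
#' @param ... `restraint_set` objects
#' @return a combined `restraint_set`
#' @export
c_restraints <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint set: %d restraints (%s)>\n", nrow(x),
              paste(sprintf("%s x%d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Contact restraints from predictions
#'
#' One distance restraint per prediction with probability above
#' `threshold`, between the representative atoms (Cbeta; Calpha for
#' glycine) of the two residues. Sigmoidal restraints are anchored at 8
#' Angstrom with slope `2 * probability` (steeper for confident contacts);
#' bounded restraints span 1.5-8.0 Angstrom with width 1 and are tagged
#' `centroid_only`.
#'
#' @param preds a `contact_pred` data.frame; positions are 1..L over the
#'   concatenated chains with the A/B boundary taken from the prediction
#'   set (chain-local residue numbers are emitted)
#' @param threshold probability threshold in \[0, 1\]
#' @param form `"sigmoid"` or `"bounded"`
#' @param resnames optional per-position residue names (1- or 3-letter)
#'   used to pick Calpha for glycine
#' @return a `restraint_set`
#' @export
contact_restraints <- function(preds, threshold = 0.5,
                               form = c("sigmoid", "bounded"),
                               resnames = NULL) {
  form <- match.arg(form)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  keep <- preds$prob > threshold
  top <- preds[keep, , drop = FALSE]
  if (nrow(top) == 0L)
    return(restraint_set(character(0), list(), numeric(0), numeric(0)))
  boundary <- attr(preds, "boundary") %||% Inf
  sel <- function(pos, chain) {
    resno <- if (chain == "B") pos - boundary else pos
    rn <- if (!is.null(resnames)) resnames[pos] else ""
    atom <- if (rn %in% c("G", "GLY")) "CA" else "CB"
    sprintf("%s:%d:%s", chain, resno, atom)
  }
  atoms <- lapply(seq_len(nrow(top)), function(k)
    c(sel(top$i[k], top$chain_i[k]), sel(top$j[k], top$chain_j[k])))
  if (form == "sigmoid") {
    restraint_set(rep("sigmoidal_distance", nrow(top)), atoms,
                  p1 = 8.0, p2 = 2 * top$prob)
  } else {
    restraint_set(rep("bounded_distance", nrow(top)), atoms,
                  p1 = 1.5, p2 = 8.0, p3 = 1.0, stage_tag = "centroid_only")
  }
}

# ---- cluster geometry -------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Cluster geometry specification
#'
#' @param mean_sg_sg mean Sgamma-Sgamma distance (Angstrom)
#' @param sg_sg_tol,angle_tol,dihedral_tol restraint widths
#' @param angles,dihedrals per-motif-position values (degrees, length 4)
#' @param source reference structure id
#' @return object of class `cluster_geometry_spec`
#' @export
cluster_geometry_spec <- function(mean_sg_sg, angles, dihedrals,
                                  sg_sg_tol = 0.5, angle_tol = 1.0,
                                  dihedral_tol = 2.3, source = "unknown") {
  stopifnot(length(angles) == 4L, length(dihedrals) == 4L)
  if (any(c(sg_sg_tol, angle_tol, dihedral_tol) <= 0))
    stop("tolerances must be positive")
  structure(list(mean_sg_sg = mean_sg_sg, angles = angles,
                 dihedrals = dihedrals, sg_sg_tol = sg_sg_tol,
                 angle_tol = angle_tol, dihedral_tol = dihedral_tol,
                 source = source),
            class = "cluster_geometry_spec")
}

#' Default 4Fe-4S cluster restraint geometry
#'
#' The published restraint block derived from a high-resolution dicluster
#' ferredoxin reference: mean Sgamma-Sgamma 6.4 +/- 0.5 Angstrom;
#' Calpha-Cbeta-Sgamma angles 114.6/116.9/112.9/108.9 +/- 1 degree and
#' C-Calpha-Cbeta-Sgamma dihedrals 56.1/-52.7/-71.6/58.4 +/- 2.3 degrees
#' per motif position.
#'
#' @return a [cluster_geometry_spec()]
#' @export
cluster_geometry_defaults <- function() {
  cluster_geometry_spec(6.4,
                        angles = c(114.6, 116.9, 112.9, 108.9),
                        dihedrals = c(56.1, -52.7, -71.6, 58.4),
                        source = "reference dicluster ferredoxin (printed defaults)")
}

#' Extract cluster geometry from a reference structure
#'
#' For each cluster (a group of four cysteines): all six Sgamma-Sgamma
#' distances; the mean is taken over both clusters (12 distances).
#' Per-motif-position Calpha-Cbeta-Sgamma angles and C-Calpha-Cbeta-Sgamma
#' dihedrals are averaged over the two clusters' corresponding residues
#' (position k of group 1 with position k of group 2).
#'
#' @param ref a [structure_coords] reference structure
#' @param groups list of two integer vectors of four cysteine residue
#'   numbers, in motif order
#' @param chain chain id of the cysteines (default "A")
#' @param source label recorded in the spec
#' @return a [cluster_geometry_spec()]
#' @export
extract_cluster_geometry <- function(ref, groups, chain = "A",
                                     source = "reference") {
  stopifnot(length(groups) == 2L, all(lengths(groups) == 4L))
  atom_xyz <- function(resno, atom) {
    hit <- ref[!ref$het & ref$chain == chain & ref$resno == resno &
                 ref$atom == atom, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop("missing atom ", atom, " in residue ", resno)
    as.numeric(hit[1, c("x", "y", "z")])
  }
  dists <- unlist(lapply(groups, function(g) {
    sg <- lapply(g, atom_xyz, atom = "SG")
    combs <- utils::combn(4L, 2L)
    apply(combs, 2L, function(p) vnorm(sg[[p[1]]] - sg[[p[2]]]))
  }))
  angles <- vapply(1:4, function(k) {
    mean(vapply(groups, function(g) {
      angle_deg(atom_xyz(g[k], "CA"), atom_xyz(g[k], "CB"),
                atom_xyz(g[k], "SG"))
    }, numeric(1)))
  }, numeric(1))
  dihedrals <- vapply(1:4, function(k) {
    # circular mean over the two clusters
    vals <- vapply(groups, function(g) {
      dihedral_deg(atom_xyz(g[k], "C"), atom_xyz(g[k], "CA"),
                   atom_xyz(g[k], "CB"), atom_xyz(g[k], "SG"))
    }, numeric(1)) * pi / 180
    atan2(mean(sin(vals)), mean(cos(vals))) * 180 / pi
  }, numeric(1))
  cluster_geometry_spec(mean(dists), angles = angles, dihedrals = dihedrals,
                        source = source)
}

#' Cluster restraints for two 4Fe-4S binding sites
#'
#' Per cluster: 6 harmonic Sgamma-Sgamma distance restraints, 4 harmonic
#' Calpha-Cbeta-Sgamma angle restraints and 4 circular-harmonic
#' C-Calpha-Cbeta-Sgamma dihedral restraints — 14 per cluster, 28 for the
#' default two clusters.
#'
#' @param spec a [cluster_geometry_spec()]
#' @param groups named list of integer vectors (4 residue numbers each, in
#'   motif order); default: the cluster-A group (20, 23, 26, 60) and
#'   cluster-B group (50, 53, 56, 30) of the reference dicluster ferredoxin
#'   numbering
#' @param chain chain id of the target cysteines (default "B")
#' @return a `restraint_set`
#' @export
cluster_restraints <- function(spec = cluster_geometry_defaults(),
                               groups = list(A = c(20L, 23L, 26L, 60L),
                                             B = c(50L, 53L, 56L, 30L)),
                               chain = "B") {
  stopifnot(inherits(spec, "cluster_geometry_spec"))
  if (any(lengths(groups) != 4L)) stop("each cluster group must have 4 residues")
  out <- list()
  for (g in groups) {
    combs <- utils::combn(4L, 2L)
    datoms <- lapply(seq_len(ncol(combs)), function(k)
      sprintf("%s:%d:SG", chain, g[combs[, k]]))
    out[[length(out) + 1L]] <- restraint_set(
      rep("harmonic_distance", 6L), datoms,
      p1 = spec$mean_sg_sg, p2 = spec$sg_sg_tol)
    aatoms <- lapply(g, function(r)
      sprintf("%s:%d:%s", chain, r, c("CA", "CB", "SG")))
    out[[length(out) + 1L]] <- restraint_set(
      rep("harmonic_angle", 4L), aatoms,
      p1 = spec$angles, p2 = spec$angle_tol)
    hatoms <- lapply(g, function(r)
      sprintf("%s:%d:%s", chain, r, c("C", "CA", "CB", "SG")))
    out[[length(out) + 1L]] <- restraint_set(
      rep("circular_harmonic_dihedral", 4L), hatoms,
      p1 = spec$dihedrals, p2 = spec$dihedral_tol)
  }
  do.call(c_restraints, out)
}

#' Corrinoid cofactor specification
#'
#' Four protein-cofactor hydrogen-bond distance restraints plus the Cys-on
#' cobalt coordination (Sgamma-Co distance and Cbeta-Sgamma-Co angle).
#'
#' @param hydrogen_bonds data.frame with columns `protein_atom`,
#'   `cofactor_atom`, `distance`, `tol`
#' @param cys_on list with `sg_co` (distance), `sg_co_tol`, `angle`
#'   (Cbeta-Sgamma-Co, degrees), `angle_tol`
#' @return object of class `corrinoid_spec`
#' @export
corrinoid_spec <- function(hydrogen_bonds, cys_on) {
  if (is.null(cys_on)) stop("corrinoid spec requires the cys_on group")
  need <- c("protein_atom", "cofactor_atom", "distance", "tol")
  if (!all(need %in% names(hydrogen_bonds)) || nrow(hydrogen_bonds) != 4L)
    stop("corrinoid spec requires exactly four hydrogen-bond restraints")
  if (!all(c("sg_co", "sg_co_tol", "angle", "angle_tol") %in% names(cys_on)))
    stop("incomplete cys_on group")
  structure(list(hydrogen_bonds = hydrogen_bonds, cys_on = cys_on),
            class = "corrinoid_spec")
}

#' Default corrinoid cofactor restraints
#'
#' Printed defaults: Thr60(OG1)-B12(N3B) 2.9 +/- 0.1; Thr66(OG1)-B12(O4)
#' 2.7 +/- 0.2; Val91(N)-B12(O4) 3.0 +/- 0.05; Ala153(N)-B12(O6R) 3.1 +/-
#' 0.2 Angstrom; Cys-on Sgamma-Co 2.5 +/- 0.1 Angstrom and Cbeta-Sgamma-Co
#' 108 +/- 5 degrees (the Cys-on cysteine is residue 93 on chain A; the
#' cofactor is residue 1 on ligand chain X).
#'
#' @return a [corrinoid_spec()]
#' @export
corrinoid_defaults <- function() {
  hb <- data.frame(
    protein_atom = c("A:60:OG1", "A:66:OG1", "A:91:N", "A:153:N"),
    cofactor_atom = c("X:1:N3B", "X:1:O4", "X:1:O4", "X:1:O6R"),
    distance = c(2.9, 2.7, 3.0, 3.1),
    tol = c(0.1, 0.2, 0.05, 0.2),
    stringsAsFactors = FALSE)
  corrinoid_spec(hb, list(sg_co = 2.5, sg_co_tol = 0.1,
                          angle = 108, angle_tol = 5,
                          cys = "A:93", co = "X:1:CO"))
}

#' Corrinoid restraints from a specification
#'
#' Emits 4 hydrogen-bond harmonic distance restraints, 1 Sgamma-Co harmonic
#' distance and 1 Cbeta-Sgamma-Co harmonic angle restraint (6 total).
#'
#' @param spec a [corrinoid_spec()]
#' @return a `restraint_set`
#' @export
corrinoid_restraints <- function(spec = corrinoid_defaults()) {
  stopifnot(inherits(spec, "corrinoid_spec"))
  hb <- spec$hydrogen_bonds
  hbr <- restraint_set(rep("harmonic_distance", 4L),
                       lapply(seq_len(4L), function(k)
                         c(hb$protein_atom[k], hb$cofactor_atom[k])),
                       p1 = hb$distance, p2 = hb$tol)
  cys <- spec$cys_on$cys %||% "A:93"
  co <- spec$cys_on$co %||% "X:1:CO"
  cysr <- restraint_set(
    c("harmonic_distance", "harmonic_angle"),
    list(c(paste0(cys, ":SG"), co),
         c(paste0(cys, ":CB"), paste0(cys, ":SG"), co)),
    p1 = c(spec$cys_on$sg_co, spec$cys_on$angle),
    p2 = c(spec$cys_on$sg_co_tol, spec$cys_on$angle_tol))
  c_restraints(hbr, cysr)
}

#' Place a rigid cofactor by anchor superposition
#'
#' Computes the Kabsch transform carrying the cofactor-frame anchor atoms
#' onto the model anchor atoms and applies it to all cofactor atoms.
#'
#' @param model a [structure_coords] model
#' @param cofactor a [structure_coords] cofactor in its reference frame
#' @param anchor_pairs data.frame with columns `model`, `cofactor` (atom
#'   selectors), at least 3 rows
#' @return list with `coords` (transformed cofactor), `rmsd` (anchor
#'   rmsd), `rotation`, `translation`
#' @export
place_cofactor <- function(model, cofactor, anchor_pairs) {
  if (nrow(anchor_pairs) < 3L) stop("need at least 3 anchor pairs")
  one <- function(coords, selector) {
    hit <- select_atoms(coords, selector)
    if (nrow(hit) == 0L) stop("empty selection: ", selector)
    as.numeric(hit[1, c("x", "y", "z")])
  }
  tgt <- t(vapply(anchor_pairs$model, function(s) one(model, s), numeric(3)))
  mob <- t(vapply(anchor_pairs$cofactor, function(s) one(cofactor, s), numeric(3)))
  fit <- kabsch_superpose(mob, tgt)
  xyz <- as.matrix(cofactor[, c("x", "y", "z")])
  moved <- sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
  out <- cofactor
  out$x <- moved[, 1]; out$y <- moved[, 2]; out$z <- moved[, 3]
  list(coords = out, rmsd = fit$rmsd, rotation = fit$rotation,
       translation = fit$translation)
}

# ---- restraint file IO -----------------------------------------------

sel_to_tokens <- function(sel) {
  p <- strsplit(sel, ":", fixed = TRUE)[[1]]
  sprintf("%s %s%s", p[3], p[2], p[1]) # "SG 23B"
}

tokens_to_sel <- function(atom, res) {
  chain <- sub("^-?[0-9]+", "", res)
  resno <- sub(paste0(chain, "$"), "", res)
  sprintf("%s:%s:%s", chain, resno, atom)
}

fmt <- function(x) sprintf("%.10g", x)

#' Write restraints as Rosetta-style constraint text
#'
#' Distances are written in Angstrom; angle and dihedral centers/widths are
#' converted to radians on output (and back on input). Bounded restraints
#' carry their `centroid_only` stage tag as a trailing `#stage=` comment.
#'
#' @param rs a `restraint_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_restraints <- function(rs, path) {
  lines <- vapply(seq_len(nrow(rs)), function(k) {
    r <- rs[k, ]
    atoms <- c(r$a1, r$a2, r$a3, r$a4)
    atoms <- atoms[!is.na(atoms)]
    toks <- paste(vapply(atoms, sel_to_tokens, character(1)), collapse = " ")
    tag <- if (r$stage_tag == "centroid_only") " #stage=centroid_only" else ""
    switch(r$kind,
      harmonic_distance = sprintf("AtomPair %s HARMONIC %s %s%s", toks,
                                  fmt(r$p1), fmt(r$p2), tag),
      bounded_distance = sprintf("AtomPair %s BOUNDED %s %s %s 0.5 contact%s",
                                 toks, fmt(r$p1), fmt(r$p2), fmt(r$p3), tag),
      sigmoidal_distance = sprintf("AtomPair %s SIGMOID %s %s%s", toks,
                                   fmt(r$p1), fmt(r$p2), tag),
      harmonic_angle = sprintf("Angle %s HARMONIC %s %s%s", toks,
                               fmt(r$p1 * pi / 180), fmt(r$p2 * pi / 180), tag),
      circular_harmonic_dihedral = sprintf(
        "Dihedral %s CIRCULARHARMONIC %s %s%s", toks,
        fmt(r$p1 * pi / 180), fmt(r$p2 * pi / 180), tag))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read restraints written by [write_restraints()]
#' @param path constraint file
#' @return a `restraint_set`
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(ln) {
    stage <- if (grepl("#stage=centroid_only", ln, fixed = TRUE))
      "centroid_only" else "all_stages"
    ln <- sub("\\s*#.*$", "", ln)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    head_type <- tok[1]
    natoms <- switch(head_type, AtomPair = 2L, Angle = 3L, Dihedral = 4L,
                     stop("unknown restraint line: ", head_type))
    atoms <- vapply(seq_len(natoms), function(k)
      tokens_to_sel(tok[2 * k], tok[2 * k + 1]), character(1))
    fn <- tok[2 * natoms + 2]
    pars <- suppressWarnings(as.numeric(tok[-seq_len(2 * natoms + 2)]))
    pars <- pars[!is.na(pars)] # drop trailing non-numeric tokens (tags)
    if (head_type == "AtomPair") {
      kind <- switch(fn, HARMONIC = "harmonic_distance",
                     BOUNDED = "bounded_distance",
                     SIGMOID = "sigmoidal_distance",
                     stop("unknown distance function: ", fn))
      p <- if (kind == "bounded_distance") pars[1:3] else c(pars[1:2], NA)
    } else {
      kind <- if (head_type == "Angle") "harmonic_angle"
              else "circular_harmonic_dihedral"
      p <- c(pars[1:2] * 180 / pi, NA)
    }
    list(kind = kind, atoms = atoms, p = p, stage = stage)
  })
  restraint_set(vapply(parsed, `[[`, character(1), "kind"),
                lapply(parsed, `[[`, "atoms"),
                p1 = vapply(parsed, function(x) x$p[1], numeric(1)),
                p2 = vapply(parsed, function(x) x$p[2], numeric(1)),
                p3 = vapply(parsed, function(x) x$p[3], numeric(1)),
                stage_tag = vapply(parsed, `[[`, character(1), "stage"))
}
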