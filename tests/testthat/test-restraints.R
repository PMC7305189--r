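test_that("restraint construction enforces kind/atom/width invariants", {
  expect_error(restraint_set("harmonic_distance", list(c("A:1:CB")), 6, 0.5),
               "atom count")
  expect_error(restraint_set("harmonic_distance",
                             list(c("A:1:CB", "A:9:CB")), 6, 0),
               "positive")
  expect_error(restraint_set("bounded_distance",
                             list(c("A:1:CB", "A:9:CB")), 9, 8, 1),
               "lower < upper")
  expect_error(restraint_set("wobbly", list(c("A:1:CB", "A:9:CB")), 1, 1),
               "unknown restraint kind")
  # zero-tolerance geometry spec rejected
  expect_error(cluster_geometry_spec(6.4, angles = rep(110, 4),
                                     dihedrals = rep(60, 4), angle_tol = 0),
               "positive")
})

test_that("contact restraints are emitted one per prediction above threshold", {
  empty <- data.frame(i = integer(0), j = integer(0),
                      chain_i = character(0), chain_j = character(0),
                      prob = numeric(0))
  expect_equal(nrow(contact_restraints(empty, 0.5)), 0L)

  preds <- data.frame(i = 1:5, j = c(10, 12, 14, 16, 18),
                      chain_i = "A", chain_j = c("A", "A", "B", "B", "B"),
                      prob = c(0.9, 0.8, 0.6, 0.4, 0.2))
  attr(preds, "boundary") <- 13
  rs <- contact_restraints(preds, 0.5, form = "sigmoid")
  expect_equal(nrow(rs), 3L)
  expect_true(all(rs$kind == "sigmoidal_distance"))
  expect_equal(rs$p1, rep(8, 3))
  expect_equal(rs$p2, 2 * c(0.9, 0.8, 0.6))
  # chain-B positions are renumbered relative to the boundary
  expect_equal(rs$a2[3], "B:1:CB")

  bounded <- contact_restraints(preds, 0.5, form = "bounded")
  expect_true(all(bounded$stage_tag == "centroid_only"))
  expect_equal(unique(bounded$p1), 1.5)
  expect_equal(unique(bounded$p2), 8.0)

  # glycine endpoints use CA
  gly <- contact_restraints(preds[1, ], 0.5,
                            resnames = c("G", rep("A", 17)))
  expect_equal(gly$a1, "A:1:CA")
  expect_equal(gly$a2, "A:10:CB")
  expect_error(contact_restraints(preds, 1.5), "threshold")
})

test_that("cluster geometry extraction matches construction and an O(n^2) oracle", {
  fd <- synthetic_ferredoxin()
  groups <- list(c(8, 11, 14, 47), c(18, 35, 38, 41))
  spec <- extract_cluster_geometry(fd, groups)

  # oracle: mean over all 12 Sgamma-Sgamma pairs, recomputed naively
  sg <- fd[fd$atom == "SG", ]
  dists <- c()
  for (g in groups) {
    pts <- lapply(g, function(r) unlist(sg[sg$resno == r, c("x", "y", "z")]))
    for (a in 1:3) for (b in (a + 1):4)
      dists <- c(dists, sqrt(sum((pts[[a]] - pts[[b]])^2)))
  }
  expect_equal(spec$mean_sg_sg, mean(dists))

  # construction targets are recovered exactly
  defaults <- cluster_geometry_defaults()
  expect_equal(spec$angles, defaults$angles, tolerance = 1e-6)
  expect_equal(spec$dihedrals, defaults$dihedrals, tolerance = 1e-6)

  # rigid-motion invariance
  set.seed(47)
  R <- random_rot(); tv <- rnorm(3, 0, 30)
  fd2 <- fd
  xyz <- as.matrix(fd[, c("x", "y", "z")]) %*% R
  fd2$x <- xyz[, 1] + tv[1]; fd2$y <- xyz[, 2] + tv[2]; fd2$z <- xyz[, 3] + tv[3]
  spec2 <- extract_cluster_geometry(fd2, groups)
  expect_equal(spec2$mean_sg_sg, spec$mean_sg_sg, tolerance = 1e-9)
  expect_equal(spec2$dihedrals, spec$dihedrals, tolerance = 1e-6)

  # constructed flat 6.4-A cluster: mean is exactly 6.4
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  r <- 6.4 / sqrt(8 / 3)
  rows <- do.call(rbind, lapply(1:4, function(k) {
    sgp <- tet[k, ] * r
    data.frame(chain = "A", resno = k, resname = "CYS",
               atom = c("C", "CA", "CB", "SG"),
               x = c(sgp[1] + 3, sgp[1] + 2, sgp[1] + 1, sgp[1]),
               y = c(sgp[2], sgp[2], sgp[2], sgp[2]),
               z = c(sgp[3] + 1, sgp[3] + 2, sgp[3] + 1, sgp[3]),
               het = FALSE)
  }))
  flat <- structure_coords(rows$chain, rows$resno, rows$resname, rows$atom,
                           rows$x, rows$y, rows$z)
  spec3 <- extract_cluster_geometry(flat, list(1:4, 1:4))
  expect_equal(spec3$mean_sg_sg, 6.4, tolerance = 1e-9)

  expect_error(extract_cluster_geometry(fd, list(c(8, 11, 14, 99),
                                                 c(18, 35, 38, 41))),
               "residue 99")
})

test_that("cluster restraints: 28 total with the documented defaults", {
  rs <- cluster_restraints()
  expect_equal(nrow(rs), 28L)
  expect_equal(sum(rs$kind == "harmonic_distance"), 12L)
  expect_equal(sum(rs$kind == "harmonic_angle"), 8L)
  expect_equal(sum(rs$kind == "circular_harmonic_dihedral"), 8L)
  expect_true(all(rs$p1[rs$kind == "harmonic_distance"] == 6.4))
  expect_true(all(rs$p2[rs$kind == "harmonic_distance"] == 0.5))
  expect_equal(rs$p1[rs$kind == "harmonic_angle"][1:4],
               c(114.6, 116.9, 112.9, 108.9))
  expect_true(all(rs$p2[rs$kind == "harmonic_angle"] == 1))
  expect_equal(rs$p1[rs$kind == "circular_harmonic_dihedral"][1:4],
               c(56.1, -52.7, -71.6, 58.4))
  expect_true(all(rs$p2[rs$kind == "circular_harmonic_dihedral"] == 2.3))
  # default cluster groups
  expect_true("B:20:SG" %in% c(rs$a1, rs$a2))
  expect_true("B:30:SG" %in% c(rs$a1, rs$a2))

  one <- cluster_restraints(groups = list(c(20L, 23L, 26L, 60L)))
  expect_equal(nrow(one), 14L)
  expect_error(cluster_restraints(groups = list(1:3)), "4 residues")
})

test_that("corrinoid restraints: 6 with printed defaults; incomplete specs error", {
  rs <- corrinoid_restraints()
  expect_equal(nrow(rs), 6L)
  hd <- rs[rs$kind == "harmonic_distance", ]
  expect_equal(nrow(hd), 5L)
  sgco <- hd[hd$a2 == "X:1:CO", ]
  expect_equal(sgco$p1, 2.5)
  expect_equal(sgco$p2, 0.1)
  ang <- rs[rs$kind == "harmonic_angle", ]
  expect_equal(ang$p1, 108)
  expect_equal(ang$p2, 5)
  expect_equal(hd$p1[1:4], c(2.9, 2.7, 3.0, 3.1))
  expect_equal(hd$p2[1:4], c(0.1, 0.2, 0.05, 0.2))

  expect_error(corrinoid_spec(corrinoid_defaults()$hydrogen_bonds, NULL),
               "cys_on")
  expect_error(corrinoid_spec(corrinoid_defaults()$hydrogen_bonds[1:3, ],
                              corrinoid_defaults()$cys_on),
               "four hydrogen-bond")
})

test_that("restraint files round-trip parameter-identically", {
  rs <- c_restraints(cluster_restraints(), corrinoid_restraints())
  p <- withr::local_tempfile(fileext = ".cst")
  write_restraints(rs, p)
  back <- read_restraints(p)
  expect_identical(back$kind, rs$kind)
  expect_identical(back$a1, rs$a1)
  expect_identical(back$a4, rs$a4)
  expect_equal(back$p1, rs$p1, tolerance = 1e-6)
  expect_equal(back$p2, rs$p2, tolerance = 1e-6)
  expect_identical(back$stage_tag, rs$stage_tag)

  # random mixed set incl. bounded + sigmoid with stage tags
  set.seed(53)
  mixed <- restraint_set(
    c("sigmoidal_distance", "bounded_distance", "harmonic_angle",
      "circular_harmonic_dihedral"),
    list(c("A:3:CB", "B:7:CB"), c("A:4:CB", "B:9:CA"),
         c("A:1:CA", "A:1:CB", "A:1:SG"),
         c("B:2:C", "B:2:CA", "B:2:CB", "B:2:SG")),
    p1 = c(8, 1.5, 101.3, -161.2), p2 = c(1.7, 8, 2.2, 4.4),
    p3 = c(NA, 1, NA, NA),
    stage_tag = c("all_stages", "centroid_only", "all_stages", "all_stages"))
  write_restraints(mixed, p)
  back2 <- read_restraints(p)
  expect_equal(back2$p1, mixed$p1, tolerance = 1e-6)
  expect_equal(back2$p3, mixed$p3, tolerance = 1e-6)
  expect_identical(back2$stage_tag, mixed$stage_tag)

  # golden formatting: frozen expected lines
  small <- restraint_set(c("harmonic_distance", "bounded_distance"),
                         list(c("B:20:SG", "B:23:SG"), c("A:2:CB", "B:5:CB")),
                         p1 = c(6.4, 1.5), p2 = c(0.5, 8), p3 = c(NA, 1),
                         stage_tag = c("all_stages", "centroid_only"))
  write_restraints(small, p)
  expect_identical(readLines(p),
                   c("AtomPair SG 20B SG 23B HARMONIC 6.4 0.5",
                     "AtomPair CB 2A CB 5B BOUNDED 1.5 8 1 0.5 contact #stage=centroid_only"))
})

test_that("cofactor placement recovers anchor transforms", {
  fd <- synthetic_ferredoxin()
  cl1_sg <- sprintf("A:%d:SG", c(8, 11, 14, 47))

  # coincident anchors: identity transform
  anch <- data.frame(model = cl1_sg, cofactor = cl1_sg)
  fit0 <- place_cofactor(fd, fd, anch)
  expect_lt(fit0$rmsd, 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  # known rigid displacement of the 'model' is recovered
  set.seed(59)
  R <- random_rot(); tv <- rnorm(3, 0, 15)
  model <- fd
  xyz <- as.matrix(fd[, c("x", "y", "z")]) %*% R
  model$x <- xyz[, 1] + tv[1]; model$y <- xyz[, 2] + tv[2]
  model$z <- xyz[, 3] + tv[3]
  fit <- place_cofactor(model, fd, anch)
  expect_lt(fit$rmsd, 1e-8)

  # placed cluster Fe atoms fall inside the anchor Sgamma bounding box
  placed <- fit$coords
  fe <- placed[placed$resno == 101 & grepl("FE", placed$atom), ]
  sg <- do.call(rbind, lapply(cl1_sg, function(s) select_atoms(model, s)))
  for (axis in c("x", "y", "z")) {
    expect_true(all(fe[[axis]] >= min(sg[[axis]]) - 1e-6))
    expect_true(all(fe[[axis]] <= max(sg[[axis]]) + 1e-6))
  }
  expect_error(place_cofactor(model, fd, anch[1:2, ]), "3 anchor")
})
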