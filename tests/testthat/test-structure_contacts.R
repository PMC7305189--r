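test_that("PDB IO round-trips coordinates", {
  fd <- synthetic_ferredoxin()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fd, p)
  back <- read_pdb(p)
  expect_equal(nrow(back), nrow(fd))
  expect_equal(back$x, fd$x, tolerance = 1e-3)
  expect_identical(back$atom, fd$atom)
  expect_identical(back$het, fd$het)
  expect_error(read_pdb("nonexistent.pdb"), "not found")
})

test_that("contact maps follow the cutoff and separation conventions", {
  two <- structure_coords(chain = "A", resno = c(1, 11), resname = "ALA",
                          atom = "CB", x = c(0, 5), y = 0, z = 0)
  expect_equal(nrow(contact_map_from_structure(two)$pairs), 1L)
  two9 <- structure_coords(chain = "A", resno = c(1, 11), resname = "ALA",
                           atom = "CB", x = c(0, 9), y = 0, z = 0)
  expect_equal(nrow(contact_map_from_structure(two9)$pairs), 0L)

  # 30-residue helix equals the brute-force all-pairs oracle (cutoff wide
  # enough that sep-7 neighbours along the helix axis qualify)
  hel <- helix_coords(30)
  cm <- contact_map_from_structure(hel, cutoff = 12, min_sep = 6)
  rep_pts <- representative_points(hel)
  expect_gt(nrow(cm$pairs), 0)
  expect_equal(cm$pairs, oracle_contacts(rep_pts, 12, 6),
               ignore_attr = TRUE)

  # rigid-motion invariance
  set.seed(17)
  R <- random_rot(); tv <- rnorm(3, 0, 20)
  hel2 <- hel
  xyz <- as.matrix(hel[, c("x", "y", "z")]) %*% R
  hel2$x <- xyz[, 1] + tv[1]; hel2$y <- xyz[, 2] + tv[2]
  hel2$z <- xyz[, 3] + tv[3]
  cm2 <- contact_map_from_structure(hel2, 12, 6)
  expect_equal(cm2$pairs, cm$pairs)

  # glycine falls back to CA; missing representative atoms warn and skip
  gly <- structure_coords(chain = "A", resno = c(1, 11, 20),
                          resname = c("GLY", "ALA", "ALA"),
                          atom = c("CA", "CB", "N"),
                          x = c(0, 5, 2), y = 0, z = 0)
  expect_warning(cm3 <- contact_map_from_structure(gly), "skipped")
  expect_equal(cm3$npos, 2L)
})

test_that("precision_at counts hits among the top-k", {
  obs <- contact_map(30, rbind(c(1, 10), c(2, 12), c(3, 14)), min_sep = 6)
  preds <- data.frame(i = c(1, 2, 3, 4), j = c(10, 12, 14, 20),
                      prob = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(precision_at(preds, obs, 3), 1.0)
  expect_equal(precision_at(preds, obs, 4), 0.75)
  none <- data.frame(i = 5:7, j = 25:27, prob = c(0.9, 0.8, 0.7))
  expect_equal(precision_at(none, obs, 3), 0.0)
  expect_warning(p <- precision_at(preds, obs, 10), "exceeds")
  expect_true(isTRUE(attr(p, "truncated")))

  # brute-force count on random scores
  set.seed(23)
  rnd <- data.frame(i = sample(1:20, 15, TRUE), j = sample(21:30, 15, TRUE),
                    prob = runif(15))
  k <- 8
  top <- rnd[order(-rnd$prob), ][1:k, ]
  obs_keys <- paste(obs$pairs[, 1], obs$pairs[, 2])
  manual <- mean(paste(top$i, top$j) %in% obs_keys)
  expect_equal(precision_at(rnd, obs, k), manual)

  # monotone check: appending worse predictions cannot raise precision@all
  better <- precision_at(preds[1:3, ], obs, 3)
  worse <- precision_at(preds, obs, 4)
  expect_lte(worse, better)
})

test_that("interdomain extraction returns exactly the straddling pairs", {
  preds <- data.frame(i = c(5, 30, 80, 100, 140, 10),
                      j = c(20, 90, 95, 150, 160, 15),
                      prob = c(0.9, 0.8, 0.9, 0.85, 0.9, 0.95))
  bounds <- list(CBD = c(1, 60), TMD = c(61, 120), B = c(121, 170))
  out <- interdomain_contacts(preds, bounds, threshold = 0.5)
  expect_setequal(out$region_pair, c("CBD-TMD", "TMD-B"))
  expect_equal(nrow(out), 2L)
  within <- interdomain_contacts(preds[c(1, 6), ], bounds)
  expect_equal(nrow(within), 0L)
  expect_error(
    interdomain_contacts(preds, list(A = c(1, 60), B = c(50, 100))),
    "overlap")
})

test_that("Rc is satisfied-count over summed probability", {
  map <- contact_map(20, rbind(c(1, 8), c(2, 10)), min_sep = 6)
  allhit <- data.frame(i = c(1, 2), j = c(8, 10), prob = c(1, 1))
  expect_equal(as.numeric(model_fit_rc(allhit, map, 2)), 1.0)
  expect_equal(attr(model_fit_rc(allhit, map, 2), "native_band"), c(0.7, 1.2))
  miss <- data.frame(i = c(3, 4), j = c(12, 15), prob = c(0.9, 0.8))
  expect_equal(as.numeric(model_fit_rc(miss, map, 2)), 0.0)
  mixed <- data.frame(i = c(1, 3, 2), j = c(8, 12, 10),
                      prob = c(0.8, 0.7, 0.5))
  # top-2 by prob: (1,8) hit and (3,12) miss; Rc = 1 / (0.8 + 0.7)
  expect_equal(as.numeric(model_fit_rc(mixed, map, 2)), 1 / 1.5)
  zero <- data.frame(i = 1, j = 8, prob = 0)
  expect_error(model_fit_rc(zero, map, 1), "probability mass")
  expect_error(model_fit_rc(mixed, map, 5), "exceeds")
})

test_that("atom selection and minimum group distances", {
  s <- structure_coords(chain = c("A", "A", "B", "B"),
                        resno = c(1, 2, 1, 1),
                        resname = c("CYS", "CYS", "SF4", "SF4"),
                        atom = c("SG", "SG", "FE1", "FE2"),
                        x = c(0, 1, 3, 10), y = c(0, 0, 4, 0), z = 0,
                        het = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(select_atoms(s, "B:*:FE*")), 2L)
  expect_equal(cofactor_distance(s, "A:1:SG", "B:*:FE*"), 5.0) # 3-4-5
  expect_equal(cofactor_distance(s, "A:1:SG", "A:1:SG"), 0.0)
  expect_error(cofactor_distance(s, "C:*:*", "B:*:FE*"), "C:\\*:\\*")
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(29)
  X <- matrix(rnorm(30, 0, 5), 10, 3)
  idfit <- kabsch_superpose(X, X)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-10)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-10)

  for (rep in 1:20) {
    R <- random_rot(); tv <- rnorm(3, 0, 10)
    Y <- sweep(X %*% R, 2, tv, "+")
    fit <- kabsch_superpose(X, Y)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(fit$rotation, R, tolerance = 1e-8)
  }

  # noisy copy: rmsd positive but within 3 sigma
  sigma <- 0.3
  for (rep in 1:30) {
    Y <- X + matrix(rnorm(30, 0, sigma), 10, 3)
    fit <- kabsch_superpose(X, Y)
    expect_gt(fit$rmsd, 0)
    expect_lt(fit$rmsd, 3 * sigma)
  }

  line <- cbind(1:5, 0, 0)
  expect_warning(dg <- kabsch_superpose(line, line), "degenerate")
  expect_true(dg$degenerate)
  expect_lt(dg$rmsd, 1e-10)
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "3 points")
})

test_that("template coverage flags unmapped interregion predictions", {
  truth <- contact_map(20, rbind(c(1, 9), c(2, 12), c(5, 18), c(3, 11)),
                       min_sep = 6)
  preds <- data.frame(i = c(1, 2, 5, 3), j = c(9, 12, 18, 11),
                      prob = c(0.9, 0.8, 0.7, 0.6))
  full <- template_coverage(preds, truth, mapping = 1:20)
  expect_equal(full$gap_score, 0)

  # template covering positions 1..10 only: predictions into 11..20 unmapped
  partial_map <- c(1:10, rep(NA, 10))
  partial <- template_coverage(preds, truth, partial_map)
  inter_frac <- mean(preds$j > 10)
  expect_gte(partial$gap_score, inter_frac)

  expect_error(template_coverage(preds[0, ], truth, 1:20), "empty")
  expect_error(template_coverage(preds, truth, rep(NA, 20)), "mapping")
})

test_that("contact map TSV round-trips", {
  cm <- contact_map(15, rbind(c(1, 9), c(2, 14)), cutoff = 7.5, min_sep = 5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, p)
  back <- read_contact_map(p)
  expect_equal(back$pairs, cm$pairs)
  expect_equal(back$cutoff, 7.5)
  expect_equal(back$min_sep, 5L)
  expect_equal(back$npos, 15)
})
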