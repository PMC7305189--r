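# Small-scale Potts fitting tests. The quantitative planted-recovery bars at
# the stated world size (L = 50, n = 4000) live in test-acceptance.R.

test_that("single-column fit recovers weighted log-frequencies", {
  set.seed(21)
  seqs <- sample(c("A", "C", "D"), 400, TRUE, prob = c(0.5, 0.3, 0.2))
  aln <- alignment(sprintf("s%d", 1:400), seqs)
  aln$weights <- rep(1, 400)
  fit <- fit_potts(aln)
  expect_equal(length(fit$couplings), 0L)
  freqs <- exp(fit$fields[1, ]) / sum(exp(fit$fields[1, ]))
  emp <- tabulate(match(seqs, coevopair:::ALPHABET), 21) / 400
  expect_lt(max(abs(freqs - emp)), 0.02)
})

test_that("coupling scores match a brute-force norm oracle", {
  # hand-assembled model: L = 4, single nonzero coupling entry
  L <- 4L; q <- 21L; P <- L * (L - 1L) / 2L
  J <- numeric(P * q * q)
  model <- structure(list(fields = matrix(0, L, q), couplings = J,
                          ncols = L, q = q), class = "potts_model")
  expect_true(all(coupling_scores(model) == 0))

  # single entry c at pair (1,3), states (2,5): S = |c| without gauge
  p <- 0 * L - 0 + (3 - 1 - 1) # 0-based pair index of (1,3)
  model$couplings[p * q * q + (5 - 1) * q + 2] <- -2.5
  S <- coupling_scores(model, gauge = FALSE)
  expect_equal(S[1, 3], 2.5)
  expect_equal(sum(S != 0), 2L) # symmetric entry only

  # random tensor: oracle recomputes per-block norms from coupling_block()
  set.seed(31)
  model$couplings <- rnorm(P * q * q)
  for (gauge in c(FALSE, TRUE)) {
    S <- coupling_scores(model, gauge = gauge)
    expect_equal(S, t(S))
    for (i in 1:3) for (j in (i + 1):4) {
      B <- coupling_block(model, i, j)[1:20, 1:20]
      if (gauge)
        B <- B - outer(rowMeans(B), rep(1, 20)) -
          outer(rep(1, 20), colMeans(B)) + mean(B)
      expect_equal(S[i, j], sqrt(sum(B^2)))
    }
  }
  # symmetry of the block accessor
  expect_equal(coupling_block(model, 3, 1), t(coupling_block(model, 1, 3)))
  expect_error(coupling_block(model, 2, 2), "diagonal")
})

test_that("APC correction matches hand computation and removes flat background", {
  cst <- matrix(1, 3, 3); diag(cst) <- 0
  expect_true(all(abs(apc_correct(cst)) < 1e-12))

  # hand-evaluated 3x3 oracle: off-diagonals (1,2,3)
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- 1; S[1, 3] <- S[3, 1] <- 2; S[2, 3] <- S[3, 2] <- 3
  A <- apc_correct(S)
  expect_equal(A[1, 2], -0.5)
  expect_equal(A[1, 3], 0.125)
  expect_equal(A[2, 3], 0.5)

  set.seed(5)
  R <- matrix(rnorm(36)^2, 6, 6); R <- R + t(R); diag(R) <- 0
  expect_equal(apc_correct(R), t(apc_correct(R)))
  expect_true(all(apc_correct(R * 0) == 0))
  expect_error(apc_correct(matrix(rnorm(12), 3, 4)), "square")
})

test_that("probability calibration is monotone in z and in Nf", {
  S <- matrix(0, 20, 20)
  S[1, 10] <- S[10, 1] <- 2
  S[2, 12] <- S[12, 2] <- 1
  p1 <- calibrate_probabilities(S, neff = 100, ncols = 20)
  expect_equal(p1$i[1], 1) # higher score first
  expect_gt(p1$prob[1], p1$prob[2])

  p_hi <- calibrate_probabilities(S, neff = 100, ncols = 20)
  p_lo <- calibrate_probabilities(S, neff = 1, ncols = 20)
  expect_gt(p_hi$prob[1], p_lo$prob[1])
  expect_error(calibrate_probabilities(S, neff = 0, ncols = 20), "positive")

  # separation filter: within-chain pairs under min_sep are dropped,
  # cross-chain pairs are exempt
  p2 <- calibrate_probabilities(S, neff = 10, ncols = 20, min_sep = 6,
                                boundary = 11)
  expect_false(any(p2$chain_i == p2$chain_j & (p2$j - p2$i) < 6))
  expect_true(any(p2$chain_i != p2$chain_j & (p2$j - p2$i) < 6))
})

test_that("strong coupling regularization shrinks all scores", {
  set.seed(77)
  toy_map <- contact_map(8, rbind(c(1, 7), c(2, 8)), min_sep = 6)
  m <- potts_from_contacts(toy_map, 1.0, seed = 78)
  aln <- sample_sequences(m, 300, seed = 79)
  aln$weights <- rep(1, 300)
  weak <- fit_potts(aln)
  strong <- fit_potts(aln, lambda_coupling = 1e4)
  expect_lt(max(coupling_scores(strong)), 1e-2)
  expect_gt(max(coupling_scores(weak)), 0.1)
})

test_that("objective decreases and column relabeling permutes scores", {
  set.seed(55)
  toy_map <- contact_map(7, rbind(c(1, 7)), min_sep = 6)
  m <- potts_from_contacts(toy_map, 1.2, seed = 56)
  aln <- sample_sequences(m, 250, seed = 57)
  aln$weights <- rep(1, 250)
  fit <- fit_potts(aln, trace = TRUE)
  expect_lt(fit$objective, fit$trace[1])
  expect_lt(abs(fit$objective - min(fit$trace)), 1e-4)

  perm <- c(3, 1, 7, 2, 6, 4, 5)
  aln_p <- aln_select_columns(aln, perm)
  aln_p$weights <- aln$weights
  fit_p <- fit_potts(aln_p)
  S <- coupling_scores(fit)
  S_p <- coupling_scores(fit_p)
  # column k of the permuted alignment is original column perm[k]
  expect_equal(S_p, S[perm, perm], tolerance = 1e-3)
})

test_that("a planted strongly-coupled pair ranks first by APC", {
  toy_map <- contact_map(10, rbind(c(2, 9)), min_sep = 6)
  m <- potts_from_contacts(toy_map, 1.5, seed = 61)
  aln <- sample_sequences(m, 1000, seed = 62)
  w <- sequence_weights(aln)
  aln$weights <- w$weights
  fit <- fit_potts(aln)
  A <- apc_correct(coupling_scores(fit))
  idx <- which(upper.tri(A), arr.ind = TRUE)
  best <- idx[which.max(A[idx]), ]
  expect_equal(unname(best), c(2, 9))
})

test_that("Potts models round-trip through the versioned binary container", {
  toy_map <- contact_map(6, rbind(c(1, 6)))
  m <- potts_from_contacts(toy_map, 0.8, seed = 81)
  m$lambda_field <- 0.01; m$lambda_coupling <- 0.05; m$neff <- 123.4
  p <- withr::local_tempfile(fileext = ".potts")
  write_potts(m, p)
  back <- read_potts(p)
  expect_equal(back$fields, m$fields)
  expect_equal(back$couplings, m$couplings)
  expect_equal(back$neff, 123.4)
  expect_equal(back$ncols, 6L)
  # wrong magic rejected
  bad <- withr::local_tempfile()
  writeLines("not a model", bad)
  expect_error(read_potts(bad), "not a serialized")
})

test_that("contact predictions round-trip through RR and TSV formats", {
  set.seed(71)
  S <- matrix(rnorm(400)^2, 20, 20); S <- S + t(S); diag(S) <- 0
  preds <- calibrate_probabilities(apc_correct(S), neff = 50, ncols = 20,
                                   boundary = 12)
  rr <- withr::local_tempfile(fileext = ".rr")
  write_casp_rr(preds, rr)
  back <- read_casp_rr(rr, boundary = 12)
  expect_equal(back$i, preds$i)
  expect_equal(back$prob, preds$prob, tolerance = 1e-5)
  expect_identical(back$chain_j, preds$chain_j)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contacts_tsv(preds, tsv)
  back2 <- read_contacts_tsv(tsv, boundary = 12)
  expect_equal(back2$apc, preds$apc, tolerance = 1e-9)
})
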