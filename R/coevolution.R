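#' Fit an L2-regularized pseudolikelihood Potts model
#'
#' Minimizes the weighted negative log-pseudolikelihood
#' \deqn{\sum_s w_s \sum_i -\log P(x_i^s \mid x_{-i}^s)}
#' over per-column fields and per-column-pair couplings on a 21-state
#' alphabet (20 amino acids + gap; 'X' is treated as gap during fitting),
#' plus L2 penalties `lambda_field * ||f||^2 + lambda_coupling * ||J||^2`.
#' Optimization is deterministic: zero initialization, L-BFGS-B, stopping on
#' relative objective decrease (`factr = 1e7`) or projected gradient norm
#' `<= 1e-5`, iteration cap `maxit`.
#'
#' @param aln an [alignment]; if it carries no `weights`, uniform weights
#'   are used (compute them first with [sequence_weights()] for the standard
#'   80%-identity reweighting)
#' @param lambda_field L2 strength on fields (default 0.01)
#' @param lambda_coupling L2 strength on couplings; default `0.01 * (L - 1)`
#' @param maxit iteration cap (default 500)
#' @param trace if TRUE, store the objective trace
#' @return object of class `potts_model`: fields (L x 21 matrix), flat
#'   coupling vector (see [coupling_block()]), lambdas, neff, convergence
#'   info
#' @export
fit_potts <- function(aln, lambda_field = 0.01, lambda_coupling = NULL,
                      maxit = 500L, trace = TRUE) {
  L <- aln_ncol(aln)
  # L = 1 is allowed: the model then has fields only, no couplings
  if (is.null(lambda_coupling)) lambda_coupling <- 0.01 * max(L - 1, 1)
  stopifnot(lambda_field >= 0, lambda_coupling >= 0)
  m <- encode_alignment(aln)
  m[m == 22L] <- 21L # unknown -> gap state for fitting
  m <- m - 1L        # 0-based for the kernel
  w <- aln$weights %||% rep(1, nseq(aln))
  q <- 21L
  npar <- L * q + (L * (L - 1L) / 2L) * q * q

  trace_env <- new.env(parent = emptyenv())
  trace_env$objs <- numeric(0)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!identical(cache$par, par)) {
      r <- potts_obj_grad_cpp(par, m, w, lambda_field, lambda_coupling)
      cache$par <- par
      cache$obj <- r$objective
      cache$grad <- r$gradient
    }
    invisible(NULL)
  }
  fn <- function(par) {
    eval_at(par)
    if (trace) trace_env$objs <- c(trace_env$objs, cache$obj)
    cache$obj
  }
  gr <- function(par) { eval_at(par); cache$grad }

  fit <- stats::optim(rep(0, npar), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7, pgtol = 1e-5,
                                     lmm = 20))
  if (fit$convergence != 0L) {
    gnorm <- max(abs(gr(fit$par)))
    stop(sprintf(
      "Potts fit did not converge within %d iterations (final max |grad| = %.3g)",
      maxit, gnorm))
  }
  structure(list(
    fields = matrix(fit$par[seq_len(L * q)], nrow = L, ncol = q, byrow = TRUE),
    couplings = fit$par[-seq_len(L * q)],
    ncols = L, q = q,
    lambda_field = lambda_field, lambda_coupling = lambda_coupling,
    neff = sum(w), objective = fit$value,
    trace = if (trace) trace_env$objs,
    counts = fit$counts),
    class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts model: L = %d, q = %d, neff = %.1f, objective = %.4f>\n",
              x$ncols, x$q, x$neff, x$objective))
  invisible(x)
}

# flat index bookkeeping: pairs (i, j), i < j, lexicographic, 0-based kernel
pair_offsets <- function(L) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE] # (row=i, col=j), i < j
}

#' Extract the 21x21 coupling block for a column pair
#'
#' Returns the matrix J such that `J[a, b]` couples state `a` at column `i`
#' with state `b` at column `j`. Symmetry holds by construction:
#' `coupling_block(m, i, j) == t(coupling_block(m, j, i))`.
#'
#' @param model a `potts_model`
#' @param i,j 1-based column indices, `i != j`
#' @return 21 x 21 numeric matrix
#' @export
coupling_block <- function(model, i, j) {
  L <- model$ncols; q <- model$q
  if (i == j) stop("diagonal pair (i, i) has no coupling")
  swap <- i > j
  if (swap) { tmp <- i; i <- j; j <- tmp }
  p <- (i - 1) * L - (i - 1) * i / 2 + (j - i - 1)
  B <- matrix(model$couplings[p * q * q + seq_len(q * q)], q, q)
  if (swap) t(B) else B
}

#' Frobenius coupling score matrix
#'
#' `S[i, j]` is the Frobenius norm of the coupling block for columns (i, j)
#' over the 20x20 amino-acid sub-block (gap state excluded by default),
#' after zero-sum gauge centering of each block. Symmetric, zero diagonal.
#'
#' @param model a `potts_model`
#' @param exclude_gap drop the gap state from the norm (default TRUE)
#' @param gauge apply zero-sum gauge centering per block (default TRUE)
#' @return L x L numeric matrix
#' @export
coupling_scores <- function(model, exclude_gap = TRUE, gauge = TRUE) {
  coupling_fronorm_cpp(model$couplings, model$ncols, exclude_gap, gauge)
}

#' Average product correction
#'
#' `S'[i, j] = S[i, j] - mean_i * mean_j / mean_all`, with means taken over
#' off-diagonal entries. Removes the uniform background (entropic and
#' phylogenetic bias) from a symmetric score matrix.
#'
#' @param S symmetric score matrix with zero diagonal
#' @return corrected matrix, symmetric with zero diagonal
#' @export
apc_correct <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  n <- nrow(S)
  if (n < 2L) return(S * 0)
  mean_i <- rowSums(S) / (n - 1)
  mean_all <- sum(S) / (n * (n - 1))
  if (mean_all == 0) return(S * 0)
  corr <- S - outer(mean_i, mean_i) / mean_all
  diag(corr) <- 0
  corr
}

#' Default contact-probability calibration coefficients
#'
#' Probability = plogis(a * z + b * log(Nf) + c), where z is the APC score
#' normalized by the mean of the top-L scores. Coefficients were fit once by
#' logistic regression on a packaged synthetic benchmark (20 replicate toy
#' complexes, planted contacts; see the methods vignette) and are frozen
#' here.
#'
#' @return named numeric vector with elements `a`, `b`, `c`
#' @export
contact_calibration_defaults <- function() {
  c(a = 2.61, b = 0.18, c = -3.56)
}

#' Calibrate contact probabilities from corrected scores
#'
#' Eligible pairs have within-chain separation `|i - j| >= min_sep`;
#' inter-chain pairs (straddling `boundary`) are exempt from the separation
#' rule. Scores are normalized by the mean of the top-`ncols` eligible
#' scores and mapped through a logistic in (z, log Nf).
#'
#' @param scores APC-corrected score matrix
#' @param neff effective number of sequences (> 0)
#' @param ncols alignment length used for Nf and for the top-L normalizer
#'   (defaults to `nrow(scores)`)
#' @param min_sep minimum within-chain separation (default 6)
#' @param boundary last column of chain A, or NULL for a single chain
#' @param coefficients calibration coefficients, see
#'   [contact_calibration_defaults()]
#' @return data.frame of class `contact_pred`, sorted by decreasing
#'   probability, with columns `i`, `j`, `chain_i`, `chain_j`, `apc`, `z`,
#'   `prob`
#' @export
calibrate_probabilities <- function(scores, neff, ncols = nrow(scores),
                                    min_sep = 6L, boundary = NULL,
                                    coefficients = contact_calibration_defaults()) {
  if (!is.numeric(neff) || neff <= 0) stop("neff must be positive")
  n <- nrow(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  if (is.null(boundary)) {
    chain_i <- chain_j <- rep("A", length(i))
    eligible <- (j - i) >= min_sep
  } else {
    chain_i <- ifelse(i <= boundary, "A", "B")
    chain_j <- ifelse(j <= boundary, "A", "B")
    eligible <- chain_i != chain_j | (j - i) >= min_sep
  }
  i <- i[eligible]; j <- j[eligible]
  chain_i <- chain_i[eligible]; chain_j <- chain_j[eligible]
  s <- scores[cbind(i, j)]
  top <- sort(s, decreasing = TRUE)[seq_len(min(ncols, length(s)))]
  denom <- mean(top)
  z <- if (denom > 0) s / denom else s * 0
  nf <- compute_nf(neff, ncols)
  co <- coefficients
  prob <- stats::plogis(co[["a"]] * z + co[["b"]] * log(nf) + co[["c"]])
  out <- data.frame(i = i, j = j, chain_i = chain_i, chain_j = chain_j,
                    apc = s, z = z, prob = prob)
  out <- out[order(-out$prob, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(boundary)) attr(out, "boundary") <- boundary
  class(out) <- c("contact_pred", "data.frame")
  out
}

#' One-call contact prediction from a weighted alignment
#'
#' Convenience wrapper: fit the Potts model, score couplings, apply APC and
#' calibrate probabilities.
#'
#' @param aln weighted [alignment] (see [sequence_weights()])
#' @param boundary chain-A length for paired alignments (defaults to the
#'   alignment's own boundary when it is a `coevo_paired`)
#' @param min_sep minimum within-chain separation
#' @param ... passed to [fit_potts()]
#' @return a `contact_pred` data.frame (see [calibrate_probabilities()])
#' @export
predict_contacts <- function(aln, boundary = NULL, min_sep = 6L, ...) {
  if (is.null(boundary) && inherits(aln, "coevo_paired")) boundary <- aln$boundary
  if (is.null(aln$weights)) {
    w <- sequence_weights(aln)
    aln$weights <- w$weights
  }
  model <- fit_potts(aln, ...)
  S <- coupling_scores(model)
  A <- apc_correct(S)
  calibrate_probabilities(A, neff = sum(aln$weights), ncols = model$ncols,
                          min_sep = min_sep, boundary = boundary)
}

# ---- model serialization ---------------------------------------------

POTTS_MAGIC <- "COEVOPOTTS"
POTTS_FORMAT_VERSION <- 1L

#' Serialize a Potts model to a versioned binary container
#'
#' Layout: magic string, format version, L, q, lambdas, neff, then the
#' field matrix and flat coupling vector as doubles (little-endian).
#'
#' @param model a `potts_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_potts <- function(model, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(POTTS_MAGIC, con, eos = NULL)
  writeBin(as.integer(c(POTTS_FORMAT_VERSION, model$ncols, model$q)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(c(model$lambda_field, model$lambda_coupling,
                        model$neff)), con, endian = "little")
  writeBin(as.numeric(t(model$fields)), con, endian = "little")
  writeBin(as.numeric(model$couplings), con, endian = "little")
  invisible(path)
}

#' Read a Potts model written by [write_potts()]
#' @param path input file
#' @return a `potts_model`
#' @export
read_potts <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(POTTS_MAGIC), useBytes = TRUE)
  if (!identical(magic, POTTS_MAGIC))
    stop("not a serialized Potts model: ", path)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != POTTS_FORMAT_VERSION)
    stop("unsupported Potts container version: ", hdr[1])
  L <- hdr[2]; q <- hdr[3]
  lam <- readBin(con, "numeric", 3L, endian = "little")
  fields <- matrix(readBin(con, "numeric", L * q, endian = "little"),
                   nrow = L, ncol = q, byrow = TRUE)
  couplings <- readBin(con, "numeric", (L * (L - 1) / 2) * q * q,
                       endian = "little")
  structure(list(fields = fields, couplings = couplings, ncols = L, q = q,
                 lambda_field = lam[1], lambda_coupling = lam[2],
                 neff = lam[3], objective = NA_real_, trace = NULL),
            class = "potts_model")
}

# ---- contact prediction IO -------------------------------------------

#' Write contact predictions in CASP-RR style
#'
#' One line per prediction: `i j 0 8 probability`.
#'
#' @param preds a `contact_pred` data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_casp_rr <- function(preds, path) {
  writeLines(sprintf("%d %d 0 8 %.6f", preds$i, preds$j, preds$prob), path)
  invisible(path)
}

#' Read contact predictions from CASP-RR style text
#' @param path input file
#' @param boundary optional chain-A length used to relabel chains
#' @return a `contact_pred` data.frame (apc/z columns NA)
#' @export
read_casp_rr <- function(path, boundary = NULL) {
  f <- utils::read.delim(path, header = FALSE, sep = "")
  out <- data.frame(i = as.integer(f[[1]]), j = as.integer(f[[2]]),
                    chain_i = "A", chain_j = "A",
                    apc = NA_real_, z = NA_real_, prob = as.numeric(f[[5]]))
  if (!is.null(boundary)) {
    out$chain_i <- ifelse(out$i <= boundary, "A", "B")
    out$chain_j <- ifelse(out$j <= boundary, "A", "B")
    attr(out, "boundary") <- boundary
  }
  out <- out[order(-out$prob, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_pred", "data.frame")
  out
}

#' Write contact predictions as TSV with chain labels
#' @param preds a `contact_pred` data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_contacts_tsv <- function(preds, path) {
  utils::write.table(as.data.frame(preds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
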