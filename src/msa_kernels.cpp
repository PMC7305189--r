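#include <Rcpp.h>
using namespace Rcpp;

// Residue codes used throughout the package:
//   1..20 amino acids in alphabet order, 21 = gap '-', 22 = unknown 'X'.
// Identity convention: matches over columns where both rows are non-gap,
// divided by columns where at least one row is non-gap. 'X' never matches
// (not even another 'X') but does count as occupancy.

static inline double pair_identity_codes(const int* a, const int* b, int L) {
  int match = 0, occ = 0;
  for (int c = 0; c < L; ++c) {
    const int x = a[c], y = b[c];
    const bool gx = (x == 21), gy = (y == 21);
    if (gx && gy) continue;
    ++occ;
    if (!gx && !gy && x == y && x != 22) ++match;
  }
  return occ > 0 ? (double)match / (double)occ : 0.0;
}

// Transpose rows into contiguous buffers once; all kernels are O(N^2 L).
static void copy_rows(const IntegerMatrix& M, std::vector<int>& buf) {
  const int N = M.nrow(), L = M.ncol();
  buf.resize((size_t)N * L);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < L; ++c)
      buf[(size_t)s * L + c] = M(s, c);
}

// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(IntegerMatrix M) {
  const int N = M.nrow(), L = M.ncol();
  std::vector<int> rows;
  copy_rows(M, rows);
  NumericMatrix out(N, N);
  for (int s = 0; s < N; ++s) {
    out(s, s) = 1.0;
    for (int t = s + 1; t < N; ++t) {
      double id = pair_identity_codes(&rows[(size_t)s * L], &rows[(size_t)t * L], L);
      out(s, t) = id;
      out(t, s) = id;
    }
  }
  return out;
}

// weight_s = 1 / #{t : identity(s,t) >= thr}, self included.
// [[Rcpp::export]]
NumericVector seq_weights_cpp(IntegerMatrix M, double thr) {
  const int N = M.nrow(), L = M.ncol();
  std::vector<int> rows;
  copy_rows(M, rows);
  std::vector<int> counts(N, 1); // self
  for (int s = 0; s < N; ++s)
    for (int t = s + 1; t < N; ++t)
      if (pair_identity_codes(&rows[(size_t)s * L], &rows[(size_t)t * L], L) >= thr) {
        ++counts[s];
        ++counts[t];
      }
  NumericVector w(N);
  for (int s = 0; s < N; ++s) w[s] = 1.0 / counts[s];
  return w;
}

// Greedy first-seen-wins redundancy filter: keep a record iff its identity
// to every previously kept record is <= max_id.
// [[Rcpp::export]]
LogicalVector greedy_filter_cpp(IntegerMatrix M, double max_id) {
  const int N = M.nrow(), L = M.ncol();
  std::vector<int> rows;
  copy_rows(M, rows);
  LogicalVector keep(N);
  std::vector<int> kept;
  kept.reserve(N);
  for (int s = 0; s < N; ++s) {
    bool ok = true;
    for (size_t k = 0; k < kept.size(); ++k) {
      if (pair_identity_codes(&rows[(size_t)s * L], &rows[(size_t)kept[k] * L], L) > max_id) {
        ok = false;
        break;
      }
    }
    keep[s] = ok;
    if (ok) kept.push_back(s);
  }
  return keep;
}
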