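#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Potts model over q = 21 states (20 amino acids + gap).
// Parameter vector layout (all column-major within blocks):
//   par[0 .. L*q)                fields f(a, i) at index a + q*i
//   par[L*q + p*q*q + a + q*b]   coupling J_p(a, b) for pair p = (i, j), i<j,
//                                a = state at column i, b = state at column j.
// Pairs are enumerated lexicographically: (0,1), (0,2), ..., (L-2, L-1).
// The symmetric tensor view is J(i,j,a,b) = J(j,i,b,a) by definition.

static inline int pair_index(int i, int j, int L) {
  // requires i < j
  return i * L - (i * (i + 1)) / 2 + (j - i - 1);
}

// Weighted negative log-pseudolikelihood + L2 penalties, with gradient.
// X is 0-based coded (0..19 aa, 20 gap); w are sequence weights. The
// objective and gradient are divided by wsum (= Neff) for optimizer
// conditioning; the penalty (lambda_f*||f||^2 + lambda_j*||J||^2) is
// divided by the same factor, i.e. the lambdas are those of the
// summed-likelihood formulation.
// [[Rcpp::export]]
List potts_obj_grad_cpp(NumericVector par, IntegerMatrix X, NumericVector w,
                        double lambda_f, double lambda_j) {
  const int q = 21;
  const int N = X.nrow(), L = X.ncol();
  const int nf = L * q;
  const size_t qq = (size_t)q * q;
  const size_t P = (size_t)L * (L - 1) / 2;
  const double* f = par.begin();
  const double* J = par.begin() + nf;

  double wsum = 0.0;
  for (int s = 0; s < N; ++s) wsum += w[s];
  if (wsum <= 0.0) stop("total sequence weight must be positive");

  // Transposed copy of every coupling block: JT_p[a + q*b] = J_p[b + q*a],
  // so that the j < i conditional reads are contiguous in the state index.
  std::vector<double> JT(P * qq);
  for (size_t p = 0; p < P; ++p) {
    const double* src = J + p * qq;
    double* dst = &JT[p * qq];
    for (int b = 0; b < q; ++b)
      for (int a = 0; a < q; ++a)
        dst[b + (size_t)q * a] = src[a + (size_t)q * b];
  }

  NumericVector grad(par.size());
  double* gf = grad.begin();
  double* gJ = grad.begin() + nf;
  std::vector<double> gJT(P * qq, 0.0); // gradient wrt JT layout (j < i terms)

  // Row-major copy of the sequences for contiguous per-sequence access.
  std::vector<int> rows((size_t)N * L);
  for (int s = 0; s < N; ++s)
    for (int i = 0; i < L; ++i)
      rows[(size_t)s * L + i] = X(s, i);

  std::vector<double> logits(q), p(q);
  double obj = 0.0;

  // Outer loop over the conditioned column keeps the working set of
  // coupling blocks (all pairs containing i) small and cache-resident.
  for (int i = 0; i < L; ++i) {
    const double* fi = f + (size_t)q * i;
    double* gfi = gf + (size_t)q * i;
    for (int s = 0; s < N; ++s) {
      const double ws = w[s];
      if (ws == 0.0) continue;
      const int* xs = &rows[(size_t)s * L];
      for (int a = 0; a < q; ++a) logits[a] = fi[a];
      for (int j = 0; j < i; ++j) {
        const double* Jp = &JT[(size_t)pair_index(j, i, L) * qq +
                               (size_t)q * xs[j]];
        for (int a = 0; a < q; ++a) logits[a] += Jp[a];
      }
      for (int j = i + 1; j < L; ++j) {
        const double* Jp = J + (size_t)pair_index(i, j, L) * qq +
                           (size_t)q * xs[j];
        for (int a = 0; a < q; ++a) logits[a] += Jp[a];
      }
      double mx = logits[0];
      for (int a = 1; a < q; ++a) if (logits[a] > mx) mx = logits[a];
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(logits[a] - mx); Z += p[a]; }
      obj += ws * (mx + std::log(Z) - logits[xs[i]]);
      const double invZ = 1.0 / Z;
      for (int a = 0; a < q; ++a) p[a] = ws * p[a] * invZ;
      p[xs[i]] -= ws; // now p[a] = ws * (P(a) - delta(a, x_i))
      for (int a = 0; a < q; ++a) gfi[a] += p[a];
      for (int j = 0; j < i; ++j) {
        double* Gp = &gJT[(size_t)pair_index(j, i, L) * qq + (size_t)q * xs[j]];
        for (int a = 0; a < q; ++a) Gp[a] += p[a];
      }
      for (int j = i + 1; j < L; ++j) {
        double* Gp = gJ + (size_t)pair_index(i, j, L) * qq + (size_t)q * xs[j];
        for (int a = 0; a < q; ++a) Gp[a] += p[a];
      }
    }
  }

  // fold the transposed-layout gradient back into the canonical layout
  for (size_t pidx = 0; pidx < P; ++pidx) {
    const double* src = &gJT[pidx * qq];
    double* dst = gJ + pidx * qq;
    for (int b = 0; b < q; ++b)
      for (int a = 0; a < q; ++a)
        dst[a + (size_t)q * b] += src[b + (size_t)q * a];
  }

  // L2 penalties and normalization
  double pen = 0.0;
  const double inv = 1.0 / wsum;
  const R_xlen_t np = par.size();
  for (R_xlen_t k = 0; k < np; ++k) {
    const double lam = (k < nf) ? lambda_f : lambda_j;
    pen += lam * par[k] * par[k];
    grad[k] = (grad[k] + 2.0 * lam * par[k]) * inv;
  }
  obj = (obj + pen) * inv;
  return List::create(_["objective"] = obj, _["gradient"] = grad);
}

// Single-chain Gibbs sampler over the 21-state Potts chain. Uses R's RNG so
// draws are reproducible under set.seed(). Returns an n x L matrix of
// 0-based state codes.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericVector par, int L, int n, int burn_in,
                               int thin) {
  const int q = 21;
  const double* f = par.begin();
  const double* J = par.begin() + (size_t)L * q;
  IntegerMatrix out(n, L);
  std::vector<int> x(L);
  std::vector<double> logits(q), p(q);

  // initial state from fields alone
  for (int i = 0; i < L; ++i) {
    const double* fi = f + (size_t)q * i;
    double mx = fi[0];
    for (int a = 1; a < q; ++a) if (fi[a] > mx) mx = fi[a];
    double Z = 0.0;
    for (int a = 0; a < q; ++a) { p[a] = std::exp(fi[a] - mx); Z += p[a]; }
    double u = unif_rand() * Z, acc = 0.0;
    int pick = q - 1;
    for (int a = 0; a < q; ++a) { acc += p[a]; if (u <= acc) { pick = a; break; } }
    x[i] = pick;
  }

  const int total = burn_in + n * thin;
  int emitted = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 0; i < L; ++i) {
      const double* fi = f + (size_t)q * i;
      for (int a = 0; a < q; ++a) logits[a] = fi[a];
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        if (i < j) {
          const double* Jp = J + (size_t)pair_index(i, j, L) * q * q + q * x[j];
          for (int a = 0; a < q; ++a) logits[a] += Jp[a];
        } else {
          const double* Jp = J + (size_t)pair_index(j, i, L) * q * q + x[j];
          for (int a = 0; a < q; ++a) logits[a] += Jp[(size_t)q * a];
        }
      }
      double mx = logits[0];
      for (int a = 1; a < q; ++a) if (logits[a] > mx) mx = logits[a];
      double Z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(logits[a] - mx); Z += p[a]; }
      double u = unif_rand() * Z, acc = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { acc += p[a]; if (u <= acc) { pick = a; break; } }
      x[i] = pick;
    }
    if (sweep >= burn_in && (sweep - burn_in) % thin == 0 && emitted < n) {
      for (int i = 0; i < L; ++i) out(emitted, i) = x[i];
      ++emitted;
    }
  }
  return out;
}

// Frobenius norms of the 20x20 amino-acid blocks after zero-sum gauge
// centering (subtract row/column means, add grand mean). Returns an L x L
// symmetric matrix with zero diagonal.
// [[Rcpp::export]]
NumericMatrix coupling_fronorm_cpp(NumericVector Jflat, int L, bool exclude_gap,
                                   bool gauge) {
  const int q = 21;
  const int qa = exclude_gap ? 20 : 21;
  NumericMatrix S(L, L);
  std::vector<double> B((size_t)qa * qa);
  int p = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j, ++p) {
      const double* Jp = Jflat.begin() + (size_t)p * q * q;
      for (int b = 0; b < qa; ++b)
        for (int a = 0; a < qa; ++a)
          B[a + (size_t)qa * b] = Jp[a + (size_t)q * b];
      if (gauge) {
        std::vector<double> rm(qa, 0.0), cm(qa, 0.0);
        double gm = 0.0;
        for (int b = 0; b < qa; ++b)
          for (int a = 0; a < qa; ++a) {
            const double v = B[a + (size_t)qa * b];
            rm[a] += v; cm[b] += v; gm += v;
          }
        for (int a = 0; a < qa; ++a) rm[a] /= qa;
        for (int b = 0; b < qa; ++b) cm[b] /= qa;
        gm /= (double)qa * qa;
        for (int b = 0; b < qa; ++b)
          for (int a = 0; a < qa; ++a)
            B[a + (size_t)qa * b] += gm - rm[a] - cm[b];
      }
      double ss = 0.0;
      for (size_t k = 0; k < B.size(); ++k) ss += B[k] * B[k];
      const double fn = std::sqrt(ss);
      S(i, j) = fn;
      S(j, i) = fn;
    }
  }
  return S;
}
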