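#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Lempel-Ziv 1976 phrase count c(n) of a binary sequence,
// Kaspar-Schuster exhaustive-history parsing.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1;    // first symbol is always a new phrase
  int i = 0;    // start of current history window
  int k = 1;    // length of current candidate extension
  int l = 1;    // start of the phrase being built
  int kmax = 1;
  while (l + k <= n) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {        // no prefix of history reproduces the phrase
        ++c;
        l += kmax;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  if (k != 1) ++c;         // unfinished phrase at the end
  return c;
}

// Rosenstein mean log-divergence curve.
// x: scalar series; m: embedding dimension; tau: delay (samples);
// theiler: temporal exclusion window; maxstep: number of divergence steps;
// max_ref: cap on the number of reference points (evenly strided subsample;
// every point still serves as a neighbour candidate).
// Returns vector of length maxstep + 1: mean over reference points of
// log(d_j(i)) for i = 0..maxstep, over pairs that stay inside the series.
// Pairs with d_j(0) == 0 are excluded.  All-excluded -> all NA.
// [[Rcpp::export(name = ".lyap_divergence_cpp")]]
NumericVector lyap_divergence_cpp(NumericVector x, int m, int tau,
                                  int theiler, int maxstep, int max_ref) {
  const int n = x.size();
  const int M = n - (m - 1) * tau;   // number of embedded points
  NumericVector out(maxstep + 1, NA_REAL);
  if (M < 2) return out;

  // contiguous point-major embedding for cache-friendly distance loops
  std::vector<double> emb((size_t)M * m);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < m; ++k)
      emb[(size_t)i * m + k] = x[i + k * tau];

  const int stride = max_ref > 0 && M > max_ref ? (M + max_ref - 1) / max_ref
                                                : 1;
  std::vector<double> acc(maxstep + 1, 0.0);
  std::vector<int> cnt(maxstep + 1, 0);
  for (int i = 0; i < M; i += stride) {
    double best = R_PosInf;
    int bi = -1;
    const double* ei = &emb[(size_t)i * m];
    for (int j = 0; j < M; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      const double* ej = &emb[(size_t)j * m];
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = ei[k] - ej[k];
        d2 += diff * diff;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bi = j; }
    }
    if (bi < 0 || best <= 0.0) continue;
    const int j = bi;
    for (int step = 0; step <= maxstep; ++step) {
      if (i + step >= M || j + step >= M) break;
      const double* a = &emb[(size_t)(i + step) * m];
      const double* b = &emb[(size_t)(j + step) * m];
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = a[k] - b[k];
        d2 += diff * diff;
      }
      if (d2 <= 0.0) break;   // trajectories collapsed; log undefined
      acc[step] += 0.5 * std::log(d2);
      cnt[step] += 1;
    }
  }
  for (int s = 0; s <= maxstep; ++s)
    if (cnt[s] > 0) out[s] = acc[s] / cnt[s];
  return out;
}
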