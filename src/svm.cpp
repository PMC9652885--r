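#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic sequential-minimal-optimization C-SVC trainer on a
// precomputed kernel.  Second index chosen as argmax |E_i - E_j| over all
// points (ties -> lowest index), so results do not depend on RNG state.
// Returns convergence when a full sweep changes no multiplier.
static void smo_core(const double* K, int n, const double* y, double C,
                     double tol, int max_sweeps,
                     std::vector<double>& alpha, double& b) {
  alpha.assign(n, 0.0);
  b = 0.0;
  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0.0) s += alpha[j] * y[j] * K[j + (size_t)n * i];
    return s;
  };
  int sweep = 0;
  while (sweep < max_sweeps) {
    int changed = 0;
    std::vector<int> cand(n);
    std::vector<double> gap(n);
    for (int i = 0; i < n; ++i) {
      const double Ei = fx(i) - y[i];
      const double r = y[i] * Ei;
      if (!((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0.0)))
        continue;
      // candidate partners in decreasing |Ei - Ej| order (ties: low index);
      // keep trying until one yields progress
      for (int t = 0; t < n; ++t) {
        cand[t] = t;
        gap[t] = t == i ? -1.0 : std::fabs(Ei - (fx(t) - y[t]));
      }
      std::stable_sort(cand.begin(), cand.end(), [&](int a, int b2) {
        return gap[a] > gap[b2];
      });
      for (int c = 0; c < n; ++c) {
        const int j = cand[c];
        if (j == i || gap[j] < 0.0) continue;
        const double Ej = fx(j) - y[j];
        const double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        const double kii = K[i + (size_t)n * i], kjj = K[j + (size_t)n * j],
                     kij = K[i + (size_t)n * j];
        const double eta = 2.0 * kij - kii - kjj;
        if (eta >= 0.0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        const double b1 = b - Ei - y[i] * (ai - ai_old) * kii -
                          y[j] * (aj - aj_old) * kij;
        const double b2 = b - Ej - y[i] * (ai - ai_old) * kij -
                          y[j] * (aj - aj_old) * kjj;
        if (ai > 0.0 && ai < C) b = b1;
        else if (aj > 0.0 && aj < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
        break;
      }
    }
    if (changed == 0) break;
    ++sweep;
  }
}

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                 int max_sweeps) {
  const int n = K.nrow();
  std::vector<double> alpha;
  double b;
  smo_core(K.begin(), n, y.begin(), C, tol, max_sweeps, alpha, b);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}

// Leave-pair-out CV engine.
// X: n x p feature matrix (raw, epoch-averaged); ypos: 1 for the positive
// (MCI) class, 0 otherwise; test_pos/test_neg: 1-based row indices of the
// held-out pair per fold.  Per fold: z-score on training rows, Fisher-score
// ranking (ties by column order), then for N = 1..maxN train an SVM on the
// top-N features and classify the two held-out subjects.
// kernel: 0 linear, 1 RBF with gamma = 1/N on z-scored features.
// Returns per-fold per-N correctness and the per-fold ranked feature ids.
// [[Rcpp::export(name = ".evaluate_cv_cpp")]]
List evaluate_cv_cpp(NumericMatrix X, IntegerVector ypos,
                     IntegerVector test_pos, IntegerVector test_neg,
                     int maxN, int kernel, double C, double tol) {
  const int n = X.nrow(), p = X.ncol();
  const int nfold = test_pos.size();
  const int Nmax = std::min(maxN, p);
  IntegerMatrix pos_correct(nfold, Nmax), neg_correct(nfold, Nmax);
  NumericMatrix pos_dec(nfold, Nmax), neg_dec(nfold, Nmax);
  IntegerMatrix sel(nfold, Nmax);
  const int ntr = n - 2;

  std::vector<int> tr(ntr);
  std::vector<double> ytr(ntr);
  std::vector<double> Z((size_t)ntr * p), zte(2 * (size_t)p);
  std::vector<double> score(p);
  std::vector<int> ord(p);
  std::vector<double> Ktr((size_t)ntr * ntr), Dtr((size_t)ntr * ntr);
  std::vector<double> Kte(2 * (size_t)ntr), Dte(2 * (size_t)ntr);
  std::vector<double> alpha;

  for (int f = 0; f < nfold; ++f) {
    const int ip = test_pos[f] - 1, in = test_neg[f] - 1;
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (i != ip && i != in) {
        tr[k] = i;
        ytr[k] = ypos[i] == 1 ? 1.0 : -1.0;
        ++k;
      }
    // z-scoring from training rows; sd == 0 -> feature zeroed out
    for (int j = 0; j < p; ++j) {
      double mu = 0.0;
      for (int i = 0; i < ntr; ++i) mu += X(tr[i], j);
      mu /= ntr;
      double ss = 0.0;
      for (int i = 0; i < ntr; ++i) {
        const double d = X(tr[i], j) - mu;
        ss += d * d;
      }
      const double sd = ntr > 1 ? std::sqrt(ss / (ntr - 1)) : 0.0;
      if (sd > 0.0) {
        for (int i = 0; i < ntr; ++i)
          Z[i + (size_t)ntr * j] = (X(tr[i], j) - mu) / sd;
        zte[0 + 2 * (size_t)j] = (X(ip, j) - mu) / sd;
        zte[1 + 2 * (size_t)j] = (X(in, j) - mu) / sd;
      } else {
        for (int i = 0; i < ntr; ++i) Z[i + (size_t)ntr * j] = 0.0;
        zte[0 + 2 * (size_t)j] = 0.0;
        zte[1 + 2 * (size_t)j] = 0.0;
      }
      // Fisher score (mu1-mu0)^2 / (v1 + v0), unbiased class variances
      double m1 = 0.0, m0 = 0.0;
      int n1 = 0, n0 = 0;
      for (int i = 0; i < ntr; ++i) {
        const double z = Z[i + (size_t)ntr * j];
        if (ytr[i] > 0) { m1 += z; ++n1; } else { m0 += z; ++n0; }
      }
      m1 /= std::max(n1, 1);
      m0 /= std::max(n0, 1);
      double v1 = 0.0, v0 = 0.0;
      for (int i = 0; i < ntr; ++i) {
        const double z = Z[i + (size_t)ntr * j];
        if (ytr[i] > 0) v1 += (z - m1) * (z - m1);
        else v0 += (z - m0) * (z - m0);
      }
      v1 = n1 > 1 ? v1 / (n1 - 1) : 0.0;
      v0 = n0 > 1 ? v0 / (n0 - 1) : 0.0;
      const double den = v1 + v0;
      score[j] = den > 0.0 ? (m1 - m0) * (m1 - m0) / den : 0.0;
    }
    for (int j = 0; j < p; ++j) ord[j] = j;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return score[a] > score[b];
    });

    std::fill(Ktr.begin(), Ktr.end(), 0.0);
    std::fill(Kte.begin(), Kte.end(), 0.0);
    std::fill(Dtr.begin(), Dtr.end(), 0.0);
    std::fill(Dte.begin(), Dte.end(), 0.0);

    for (int N = 1; N <= Nmax; ++N) {
      const int j = ord[N - 1];
      sel(f, N - 1) = j + 1;
      const double* zj = &Z[(size_t)ntr * j];
      const double t0 = zte[0 + 2 * (size_t)j], t1 = zte[1 + 2 * (size_t)j];
      if (kernel == 0) {
        for (int a = 0; a < ntr; ++a) {
          for (int b2 = 0; b2 <= a; ++b2) {
            const double v = zj[a] * zj[b2];
            Ktr[a + (size_t)ntr * b2] += v;
            if (a != b2) Ktr[b2 + (size_t)ntr * a] += v;
          }
          Kte[0 + 2 * (size_t)a] += t0 * zj[a];
          Kte[1 + 2 * (size_t)a] += t1 * zj[a];
        }
      } else {
        for (int a = 0; a < ntr; ++a) {
          for (int b2 = 0; b2 <= a; ++b2) {
            const double d = zj[a] - zj[b2];
            Dtr[a + (size_t)ntr * b2] += d * d;
            if (a != b2) Dtr[b2 + (size_t)ntr * a] += d * d;
          }
          double d = t0 - zj[a];
          Dte[0 + 2 * (size_t)a] += d * d;
          d = t1 - zj[a];
          Dte[1 + 2 * (size_t)a] += d * d;
        }
        const double g = 1.0 / N;
        for (size_t q = 0; q < Ktr.size(); ++q) Ktr[q] = std::exp(-g * Dtr[q]);
        for (size_t q = 0; q < Kte.size(); ++q) Kte[q] = std::exp(-g * Dte[q]);
      }
      double b;
      smo_core(Ktr.data(), ntr, ytr.data(), C, tol, 200, alpha, b);
      double fpos = b, fneg = b;
      for (int a = 0; a < ntr; ++a) {
        if (alpha[a] > 0.0) {
          fpos += alpha[a] * ytr[a] * Kte[0 + 2 * (size_t)a];
          fneg += alpha[a] * ytr[a] * Kte[1 + 2 * (size_t)a];
        }
      }
      pos_correct(f, N - 1) = fpos >= 0.0 ? 1 : 0;
      neg_correct(f, N - 1) = fneg < 0.0 ? 1 : 0;
      pos_dec(f, N - 1) = fpos;
      neg_dec(f, N - 1) = fneg;
    }
  }
  return List::create(_["pos_correct"] = pos_correct,
                      _["neg_correct"] = neg_correct, _["selected"] = sel,
                      _["pos_decision"] = pos_dec,
                      _["neg_decision"] = neg_dec);
}
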