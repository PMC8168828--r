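#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Dual coordinate descent for L2-regularized L1-loss (hinge) linear SVC:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// solved in the dual with one alpha per document (Hsieh et al. 2008, the
// liblinear algorithm). Xt holds one *column per document* (CSC gives cheap
// per-document access); the caller appends a constant feature so the
// intercept is part of w.
//
// Documents are visited in a freshly shuffled order each epoch; the shuffle
// uses a private SplitMix64/LCG stream seeded from `seed`, so results are
// bit-reproducible and independent of R's RNG state.

static inline std::uint64_t next_state(std::uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return s;
}

// [[Rcpp::export]]
List dcd_svm_fit(S4 Xt, NumericVector y, double C, double tol,
                 int max_epochs, int seed) {
  IntegerVector dims = Xt.slot("Dim");
  const int nfeat = dims[0], n = dims[1];
  IntegerVector Xi = Xt.slot("i");
  IntegerVector Xp = Xt.slot("p");
  NumericVector Xx = Xt.slot("x");

  if (y.size() != n) stop("label length does not match document count");

  std::vector<double> w(nfeat, 0.0), alpha(n, 0.0), qii(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int k = Xp[j]; k < Xp[j + 1]; ++k) s += Xx[k] * Xx[k];
    qii[j] = s;
  }

  std::vector<int> order(n);
  for (int j = 0; j < n; ++j) order[j] = j;
  std::uint64_t state = static_cast<std::uint64_t>(seed) * 2862933555777941757ULL
                        + 3037000493ULL;

  int epoch = 0;
  bool converged = false;
  double violation = R_PosInf;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle from the private stream
    for (int j = n - 1; j > 0; --j) {
      int k = static_cast<int>(next_state(state) >> 33) % (j + 1);
      std::swap(order[j], order[k]);
    }
    double pg_max = -R_PosInf, pg_min = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      if (qii[i] <= 0.0) continue;  // all-zero document: alpha stays 0
      double g = 0.0;
      for (int k = Xp[i]; k < Xp[i + 1]; ++k) g += w[Xi[k]] * Xx[k];
      g = y[i] * g - 1.0;

      double pg = g;
      if (alpha[i] <= 0.0)      pg = g < 0.0 ? g : 0.0;
      else if (alpha[i] >= C)   pg = g > 0.0 ? g : 0.0;
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;

      if (pg > 1e-12 || pg < -1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0)
          for (int k = Xp[i]; k < Xp[i + 1]; ++k) w[Xi[k]] += d * Xx[k];
      }
    }
    violation = pg_max - pg_min;
    if (violation < tol) { converged = true; ++epoch; break; }
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["epochs"] = epoch,
                      _["converged"] = converged,
                      _["violation"] = violation);
}
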