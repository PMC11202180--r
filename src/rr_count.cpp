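#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Count recurrence pairs of an embedded trajectory at each threshold of a
// sorted ladder, without materializing the n x n matrix.
//
// x: phase-space points (rows = time, cols = embedding coordinates)
// eps: increasing thresholds
// theiler: a pair (i, j) is counted only when |i - j| >= theiler
// chebyshev: use the max-norm instead of the Euclidean norm
//
// Returns, for each threshold, the number of unordered pairs i < j with
// distance <= eps[k] (the symmetric matrix has twice this many off-diagonal
// recurrences; diagonal cells are handled by the caller).
//
// Squared distances are compared against squared thresholds (no sqrt), and
// each pair is binned with a lookup table over [0, eps_max]; only the rare
// pair whose bin straddles a threshold falls back to a binary search.
// [[Rcpp::export]]
NumericVector rr_count_pairs(NumericMatrix x, NumericVector eps,
                             int theiler, bool chebyshev) {
  const int n = x.nrow();
  const int m = x.ncol();
  const int K = eps.size();
  std::vector<double> cut(K);
  for (int k = 0; k < K; ++k) cut[k] = chebyshev ? eps[k] : eps[k] * eps[k];
  const double cutmax = cut[K - 1];
  const int B = 8192;
  const bool use_lut = cutmax > 0;
  const double scale = use_lut ? B / cutmax : 0.0;
  std::vector<int> lut_lo(B), lut_hi(B);
  if (use_lut) {
    for (int b = 0; b < B; ++b) {
      double lo = b / scale, hi = (b + 1) / scale;
      lut_lo[b] = std::lower_bound(cut.begin(), cut.end(), lo) - cut.begin();
      lut_hi[b] = std::lower_bound(cut.begin(), cut.end(), hi) - cut.begin();
    }
  }
  std::vector<double> hist(K + 1, 0.0);
  const int jmin = std::max(theiler, 1);
  const double* X = REAL(x);
  if (m == 2 && !chebyshev) {
    // dominant case (embedding dimension 2, Euclidean norm): unrolled
    const double* c0 = X;
    const double* c1 = X + n;
    for (int i = 0; i < n; ++i) {
      const double xi = c0[i], yi = c1[i];
      for (int j = i + jmin; j < n; ++j) {
        double dx = xi - c0[j], dy = yi - c1[j];
        double d2 = dx * dx + dy * dy;
        if (d2 > cutmax) { hist[K] += 1.0; continue; }
        int idx;
        if (use_lut) {
          int b = (int)(d2 * scale); if (b >= B) b = B - 1;
          idx = (lut_lo[b] == lut_hi[b]) ? lut_lo[b]
            : (int)(std::lower_bound(cut.begin(), cut.end(), d2) -
                    cut.begin());
        } else {
          idx = (int)(std::lower_bound(cut.begin(), cut.end(), d2) -
                      cut.begin());
        }
        hist[idx] += 1.0;
      }
    }
  } else {
    for (int i = 0; i < n; ++i) {
      for (int j = i + jmin; j < n; ++j) {
        double d = 0.0;
        if (chebyshev) {
          for (int c = 0; c < m; ++c) {
            double diff = std::abs(X[c * n + i] - X[c * n + j]);
            if (diff > d) d = diff;
          }
        } else {
          for (int c = 0; c < m; ++c) {
            double diff = X[c * n + i] - X[c * n + j];
            d += diff * diff;
          }
        }
        if (d > cutmax) { hist[K] += 1.0; continue; }
        int idx;
        if (use_lut) {
          int b = (int)(d * scale); if (b >= B) b = B - 1;
          idx = (lut_lo[b] == lut_hi[b]) ? lut_lo[b]
            : (int)(std::lower_bound(cut.begin(), cut.end(), d) -
                    cut.begin());
        } else {
          idx = (int)(std::lower_bound(cut.begin(), cut.end(), d) -
                      cut.begin());
        }
        hist[idx] += 1.0;
      }
    }
  }
  NumericVector out(K);
  double acc = 0.0;
  for (int k = 0; k < K; ++k) { acc += hist[k]; out[k] = acc; }
  return out;
}
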