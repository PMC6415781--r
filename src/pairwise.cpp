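#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise trajectory dissimilarity (normalized separation standard
// deviation) for an n x T x d positions array:
//   a_ij = sqrt( sum_k (rbar - r_k)^2 ) / rbar
//        = sqrt( max(S2 - S1^2 / T, 0) ) / (S1 / T)
// with S1 = sum_k r_k, S2 = sum_k r_k^2 and minimum-image distances in
// periodic dimensions. Coincident pairs (S1 == 0) get a_ij = 0 and are
// counted for the caller to warn about.
// [[Rcpp::export]]
List cpp_trajectory_adjacency(NumericVector positions, NumericVector periodic) {
  IntegerVector dm = positions.attr("dim");
  const int n = dm[0], T = dm[1], d = dm[2];

  // repack state-major: P[i][k*d + dd] for cache-friendly pair scans
  std::vector<double> P((size_t)n * T * d);
  for (int dd = 0; dd < d; ++dd)
    for (int k = 0; k < T; ++k) {
      const double *src = &positions[(size_t)k * n + (size_t)dd * n * T];
      for (int i = 0; i < n; ++i)
        P[(size_t)i * T * d + (size_t)k * d + dd] = src[i];
    }

  std::vector<double> L(d);
  std::vector<bool> isper(d);
  for (int dd = 0; dd < d; ++dd) {
    isper[dd] = R_finite(periodic[dd]);
    L[dd] = isper[dd] ? periodic[dd] : 0.0;
  }

  NumericMatrix A(n, n);
  int n_coincident = 0;
  for (int i = 0; i < n - 1; ++i) {
    const double *pi = &P[(size_t)i * T * d];
    for (int j = i + 1; j < n; ++j) {
      const double *pj = &P[(size_t)j * T * d];
      double s1 = 0.0, s2 = 0.0;
      for (int k = 0; k < T; ++k) {
        double r2 = 0.0;
        const double *a = pi + (size_t)k * d, *b = pj + (size_t)k * d;
        for (int dd = 0; dd < d; ++dd) {
          double delta = a[dd] - b[dd];
          if (isper[dd]) delta -= L[dd] * std::round(delta / L[dd]);
          r2 += delta * delta;
        }
        double r = std::sqrt(r2);
        s1 += r;
        s2 += r * r;
      }
      double val;
      if (s1 == 0.0) {
        val = 0.0;
        ++n_coincident;
      } else {
        double rbar = s1 / T;
        double ss = s2 - s1 * s1 / T;
        val = std::sqrt(ss > 0.0 ? ss : 0.0) / rbar;
      }
      A(i, j) = val;
      A(j, i) = val;
    }
  }
  return List::create(_["adjacency"] = A, _["n_coincident"] = n_coincident);
}
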