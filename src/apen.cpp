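#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Approximate entropy (Pincus): ApEn = Phi^m(r) - Phi^{m+1}(r), with
// Phi^m(r) the mean over templates of log(C_i^m), C_i^m the fraction of
// templates (self-match included) within Chebyshev distance r.
//
// Pair search is pruned by sorting template start positions on their first
// coordinate: |x[t] - x[u]| <= r is necessary for any template match, so a
// two-pointer sweep over the sorted order visits only candidate pairs.
// Counts for dimensions m and m+1 are accumulated in one sweep. For the
// common m = 2 case the remaining coordinates are gathered into
// sorted-order arrays so the hot loop runs branch-free over contiguous
// memory.
//
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;   // number of m-dimensional templates
  const int nm1 = n - m;      // number of (m+1)-dimensional templates
  if (m < 1) stop("embedding dimension m must be >= 1");
  if (nm1 < 1) stop("series too short for embedding dimension m");
  if (r < 0) stop("tolerance r must be non-negative");

  std::vector<int> idx(nm);
  for (int i = 0; i < nm; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  // self-matches included; counts accumulated in sorted order
  std::vector<double> cs(nm, 1.0), cs1(nm, 0.0);

  if (m == 2) {
    // gather trailing coordinates in sorted order for sequential access
    std::vector<double> s0(nm), s1(nm), s2(nm);
    std::vector<unsigned char> ok1(nm);
    for (int a = 0; a < nm; ++a) {
      const int t = idx[a];
      s0[a] = x[t];
      s1[a] = x[t + 1];
      s2[a] = (t < nm1) ? x[t + 2] : 0.0;
      ok1[a] = (t < nm1) ? 1 : 0;  // template valid in dimension m + 1
      cs1[a] = ok1[a] ? 1.0 : 0.0;
    }
    for (int a = 0; a < nm; ++a) {
      const double x0 = s0[a], x1 = s1[a], x2 = s2[a];
      const unsigned char oa = ok1[a];
      double acc2 = 0.0, acc3 = 0.0;
      for (int b = a + 1; b < nm; ++b) {
        if (s0[b] - x0 > r) break;
        const double m2 = (std::fabs(s1[b] - x1) <= r) ? 1.0 : 0.0;
        const double m3 =
            m2 * ((oa & ok1[b]) && std::fabs(s2[b] - x2) <= r ? 1.0 : 0.0);
        acc2 += m2;
        acc3 += m3;
        cs[b] += m2;
        cs1[b] += m3;
      }
      cs[a] += acc2;
      cs1[a] += acc3;
    }
  } else {
    for (int a = 0; a < nm; ++a) {
      if (idx[a] < nm1) cs1[a] = 1.0;  // self-match for valid templates
    }
    for (int a = 0; a < nm; ++a) {
      const int t = idx[a];
      const double xt = x[t];
      for (int b = a + 1; b < nm; ++b) {
        const int u = idx[b];
        if (x[u] - xt > r) break;
        bool ok = true;
        for (int k = 1; k < m; ++k) {
          if (std::fabs(x[t + k] - x[u + k]) > r) { ok = false; break; }
        }
        if (!ok) continue;
        cs[a] += 1.0;
        cs[b] += 1.0;
        if (t < nm1 && u < nm1 && std::fabs(x[t + m] - x[u + m]) <= r) {
          cs1[a] += 1.0;
          cs1[b] += 1.0;
        }
      }
    }
  }

  double phim = 0.0, phim1 = 0.0;
  for (int a = 0; a < nm; ++a) {
    phim += std::log(cs[a] / nm);
    if (cs1[a] > 0.0) phim1 += std::log(cs1[a] / nm1);
  }
  phim /= nm;
  phim1 /= nm1;
  return phim - phim1;
}
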