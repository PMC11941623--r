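#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in (maximum likelihood) pairwise mutual information in bits for all
// unordered pairs of rows of a discretized matrix. `bins` uses 0-based
// labels in [0, n_bins). The diagonal holds marginal entropies H(X) = I(X;X).
// Optional Miller-Madow correction: I += (Kxy - Kx - Ky + 1) / (2 n ln 2).
// [[Rcpp::export]]
NumericMatrix pairwise_mi_cpp(IntegerMatrix bins, int n_bins,
                              bool miller_madow) {
  const int g = bins.nrow();
  const int n = bins.ncol();
  const double inv_n = 1.0 / n;
  const double mm_unit = 1.0 / (2.0 * n * std::log(2.0));
  NumericMatrix out(g, g);

  // row-major copy for cache-friendly pair scans
  std::vector<int> B((size_t)g * n);
  for (int i = 0; i < g; ++i)
    for (int s = 0; s < n; ++s)
      B[(size_t)i * n + s] = bins(i, s);

  std::vector<double> hx(g);
  std::vector<int> kx(g);
  {
    std::vector<int> cnt(n_bins);
    for (int i = 0; i < g; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0);
      const int *bi = &B[(size_t)i * n];
      for (int s = 0; s < n; ++s) cnt[bi[s]]++;
      double h = 0.0;
      int k = 0;
      for (int b = 0; b < n_bins; ++b)
        if (cnt[b] > 0) {
          const double p = cnt[b] * inv_n;
          h -= p * std::log2(p);
          ++k;
        }
      hx[i] = h;
      kx[i] = k;
    }
  }

  std::vector<int> joint((size_t)n_bins * n_bins);
  for (int i = 0; i < g; ++i) {
    out(i, i) = hx[i];
    const int *bi = &B[(size_t)i * n];
    for (int j = i + 1; j < g; ++j) {
      const int *bj = &B[(size_t)j * n];
      std::fill(joint.begin(), joint.end(), 0);
      for (int s = 0; s < n; ++s) joint[bi[s] * n_bins + bj[s]]++;
      double hxy = 0.0;
      int kxy = 0;
      const int cells = n_bins * n_bins;
      for (int c = 0; c < cells; ++c)
        if (joint[c] > 0) {
          const double p = joint[c] * inv_n;
          hxy -= p * std::log2(p);
          ++kxy;
        }
      double mi = hx[i] + hx[j] - hxy;
      if (miller_madow) mi += (kxy - kx[i] - kx[j] + 1) * mm_unit;
      if (mi < 0.0) mi = 0.0;
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}
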