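#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// declared in convolve3d.cpp
NumericVector conv3d_sep(NumericVector x, IntegerVector dims,
                         NumericVector k1, NumericVector k2,
                         NumericVector k3, int boundary);

// one smoothed, mask-standardized Gaussian field; draws from R's RNG so a
// set.seed() call in R makes the whole simulation reproducible
static std::vector<double> null_field(const IntegerVector& dims,
                                      const NumericVector& k1,
                                      const NumericVector& k2,
                                      const NumericVector& k3,
                                      const IntegerVector& vox) {
  int nv = dims[0] * dims[1] * dims[2];
  NumericVector noise = rnorm(nv);
  NumericVector sm = conv3d_sep(noise, dims, k1, k2, k3, 1);
  int m = vox.size();
  std::vector<double> z(m);
  double mean = 0.0;
  for (int i = 0; i < m; ++i) { z[i] = sm[vox[i] - 1]; mean += z[i]; }
  mean /= m;
  double ss = 0.0;
  for (int i = 0; i < m; ++i) { z[i] -= mean; ss += z[i] * z[i]; }
  double sd = std::sqrt(ss / (m - 1));
  for (int i = 0; i < m; ++i) z[i] /= sd;
  return z;
}

// suffix-sum histogram: counts[j] = #(x > u_asc[j]) for ascending u_asc
static void count_above(const std::vector<double>& x,
                        const NumericVector& u_asc,
                        std::vector<int>& counts) {
  int K = u_asc.size();
  std::fill(counts.begin(), counts.end(), 0);
  std::vector<int> tab(K + 1, 0);
  for (size_t i = 0; i < x.size(); ++i) {
    int bin = std::upper_bound(u_asc.begin(), u_asc.end(), x[i]) -
      u_asc.begin();
    ++tab[bin];
  }
  int acc = 0;
  for (int j = K; j >= 1; --j) {
    acc += tab[j];
    counts[j - 1] = acc;
  }
}

// Monte Carlo null overlap percentages: two direction-pairs per iteration,
// member A smoothed with kernels ka*, member B with kb*; overlap percent of
// A's suprathreshold voxels, averaged over the pairs. u_asc must be the
// ladder's Gaussian thresholds sorted ascending; the output column order
// matches u_asc (the caller reorders to ladder order).
// [[Rcpp::export]]
NumericMatrix null_overlap_block(int n_iterations, IntegerVector dims,
                                 NumericVector k1a, NumericVector k2a,
                                 NumericVector k3a, NumericVector k1b,
                                 NumericVector k2b, NumericVector k3b,
                                 IntegerVector vox, NumericVector u_asc) {
  int K = u_asc.size();
  NumericMatrix out(n_iterations, K);
  std::vector<int> n_a(K), n_int(K);
  std::vector<double> zmin(vox.size());
  for (int it = 0; it < n_iterations; ++it) {
    std::vector<double> acc(K, 0.0);
    std::vector<int> ndef(K, 0);
    for (int pair = 0; pair < 2; ++pair) {
      std::vector<double> a = null_field(dims, k1a, k2a, k3a, vox);
      std::vector<double> b = null_field(dims, k1b, k2b, k3b, vox);
      for (size_t i = 0; i < a.size(); ++i) zmin[i] = std::min(a[i], b[i]);
      count_above(a, u_asc, n_a);
      count_above(zmin, u_asc, n_int);
      for (int j = 0; j < K; ++j) {
        if (n_a[j] > 0) {
          acc[j] += 100.0 * n_int[j] / n_a[j];
          ++ndef[j];
        }
      }
    }
    for (int j = 0; j < K; ++j)
      out(it, j) = ndef[j] > 0 ? acc[j] / ndef[j] : NA_REAL;
    if (it % 256 == 0) checkUserInterrupt();
  }
  return out;
}
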