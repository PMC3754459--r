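#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 3D convolution of a dense lattice with per-axis 1D kernels.
// boundary: 0 = half-sample symmetric reflection (x[-1] = x[0]), which
// conserves the total sum for normalized symmetric kernels; 1 = periodic
// wrap, which makes smoothed white noise exactly stationary (used by the
// Monte Carlo null field generator).

static inline int edge_index(int i, int n, int boundary) {
  if (boundary) {                 // periodic
    i %= n;
    if (i < 0) i += n;
    return i;
  }
  while (i < 0 || i >= n) {       // half-sample symmetric
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void conv_axis(const double* in, double* out,
                      int n1, int n2, int n3, int axis,
                      const double* k, int klen, int boundary) {
  int r = (klen - 1) / 2;
  if (axis == 0) {
    // line-wise with a padded contiguous buffer
    std::vector<double> buf(n1 + 2 * r);
    for (int z = 0; z < n3; ++z) {
      for (int y = 0; y < n2; ++y) {
        const double* col = in + (size_t)(z * n2 + y) * n1;
        double* ocol = out + (size_t)(z * n2 + y) * n1;
        for (int i = 0; i < r; ++i) {
          buf[i] = col[edge_index(i - r, n1, boundary)];
          buf[n1 + r + i] = col[edge_index(n1 + i, n1, boundary)];
        }
        std::copy(col, col + n1, buf.begin() + r);
        for (int x = 0; x < n1; ++x) {
          double acc = 0.0;
          const double* b = &buf[x];
          for (int j = 0; j < klen; ++j) acc += k[j] * b[j];
          ocol[x] = acc;
        }
      }
    }
  } else if (axis == 1) {
    // row-accumulation within each z-plane (rows are contiguous)
    size_t plane = (size_t)n1 * n2;
    for (int z = 0; z < n3; ++z) {
      const double* pl = in + plane * z;
      double* opl = out + plane * z;
      std::fill(opl, opl + plane, 0.0);
      for (int y = 0; y < n2; ++y) {
        double* orow = opl + (size_t)y * n1;
        for (int j = 0; j < klen; ++j) {
          int yi = edge_index(y + j - r, n2, boundary);
          const double* row = pl + (size_t)yi * n1;
          double kj = k[j];
          for (int x = 0; x < n1; ++x) orow[x] += kj * row[x];
        }
      }
    }
  } else {
    // plane-accumulation along z (planes are contiguous)
    size_t plane = (size_t)n1 * n2;
    for (int z = 0; z < n3; ++z) {
      double* opl = out + plane * z;
      for (int j = 0; j < klen; ++j) {
        int zi = edge_index(z + j - r, n3, boundary);
        const double* pl = in + plane * zi;
        double kj = k[j];
        if (j == 0)
          for (size_t i = 0; i < plane; ++i) opl[i] = kj * pl[i];
        else
          for (size_t i = 0; i < plane; ++i) opl[i] += kj * pl[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_sep(NumericVector x, IntegerVector dims,
                         NumericVector k1, NumericVector k2,
                         NumericVector k3, int boundary = 0) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if ((size_t)x.size() != (size_t)n1 * n2 * n3)
    stop("length of x does not match dims");
  NumericVector a = clone(x);
  NumericVector b(x.size());
  double* src = REAL(a);
  double* dst = REAL(b);
  bool result_in_a = true;
  const NumericVector* kern[3] = { &k1, &k2, &k3 };
  for (int axis = 0; axis < 3; ++axis) {
    if (kern[axis]->size() > 1) {
      conv_axis(src, dst, n1, n2, n3, axis,
                REAL(*kern[axis]), kern[axis]->size(), boundary);
      std::swap(src, dst);
      result_in_a = !result_in_a;
    }
  }
  return result_in_a ? a : b;
}
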