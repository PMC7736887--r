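#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Convolve a 3D array along one axis with a centered odd-length kernel,
// zero boundary condition. `axis` is 1-based. The array is viewed as
// [A, L, B] with A = stride-1 block before the axis, L = axis length,
// B = trailing block, so the inner loop is always contiguous.
// [[Rcpp::export]]
NumericVector conv3d_axis(NumericVector x, IntegerVector dims,
                          NumericVector kernel, int axis) {
  const int ax = axis - 1;
  long long A = 1, B = 1;
  for (int a = 0; a < ax; ++a) A *= dims[a];
  for (int a = ax + 1; a < 3; ++a) B *= dims[a];
  const long long L = dims[ax];
  const int K = kernel.size(), h = K / 2;
  NumericVector out(x.size());
  const double *px = x.begin(), *pk = kernel.begin();
  double *po = out.begin();
  for (long long b = 0; b < B; ++b) {
    const double *xb = px + b * A * L;
    double *ob = po + b * A * L;
    for (long long i = 0; i < L; ++i) {
      const int kmin = (int)std::max(0LL, h - i);
      const int kmax = (int)std::min((long long)K - 1, L - 1 + h - i);
      double *oi = ob + i * A;
      for (int k = kmin; k <= kmax; ++k) {
        const double w = pk[k];
        const double *xs = xb + (i + k - h) * A;
        for (long long a = 0; a < A; ++a) oi[a] += w * xs[a];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// For each target voxel (0-based index triples, n x 3), mean of `x` over
// all in-grid voxels displaced by `offsets` (m x 3, 0-based deltas).
// [[Rcpp::export]]
NumericVector kernel_means(NumericVector x, IntegerVector dims,
                           IntegerMatrix targets, IntegerMatrix offsets) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int n = targets.nrow(), m = offsets.nrow();
  NumericVector out(n);
  const double *px = x.begin();
  for (int t = 0; t < n; ++t) {
    const int ti = targets(t, 0), tj = targets(t, 1), tk = targets(t, 2);
    double acc = 0.0;
    int cnt = 0;
    for (int q = 0; q < m; ++q) {
      const int i = ti + offsets(q, 0);
      const int j = tj + offsets(q, 1);
      const int k = tk + offsets(q, 2);
      if (i < 0 || i >= d0 || j < 0 || j >= d1 || k < 0 || k >= d2) continue;
      acc += px[(long long)i + (long long)d0 * j + (long long)d0 * d1 * k];
      ++cnt;
    }
    out[t] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}
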