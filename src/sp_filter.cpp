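#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D min-plus convolution with the parabola c*k^2 (grey-scale erosion by a
// parabolic structuring element), computed exactly in O(n) with the lower
// envelope of parabolas (the generalized distance transform).
static void parabolic_erode_1d(const double *f, double *d, int n, double c,
                               int *v, double *z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int vk = v[k];
      s = ((f[q] + c * (double)q * q) - (f[vk] + c * (double)vk * vk)) /
          (2.0 * c * (q - vk));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int p = 0; p < n; ++p) {
    while (z[k + 1] < p) ++k;
    int vq = v[k];
    d[p] = f[vq] + c * (double)(p - vq) * (p - vq);
  }
}

// Erode a matrix in place with the separable paraboloid b(u,v) = -c(u^2+v^2):
// min-plus convolution along columns, then along rows.
static void parabolic_erode_mat(std::vector<double> &m, int nr, int nc,
                                double c) {
  int nmax = nr > nc ? nr : nc;
  std::vector<double> buf(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int j = 0; j < nc; ++j) {
    double *col = m.data() + (size_t)j * nr;
    parabolic_erode_1d(col, out.data(), nr, c, v.data(), z.data());
    std::copy(out.begin(), out.begin() + nr, col);
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m[(size_t)j * nr + i];
    parabolic_erode_1d(buf.data(), out.data(), nc, c, v.data(), z.data());
    for (int j = 0; j < nc; ++j) m[(size_t)j * nr + i] = out[j];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_parabola_opening(NumericMatrix img, double curvature) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> m(img.begin(), img.end());
  // opening = dilation of the erosion; dilation is erosion of the negated image
  parabolic_erode_mat(m, nr, nc, curvature);
  for (size_t i = 0; i < m.size(); ++i) m[i] = -m[i];
  parabolic_erode_mat(m, nr, nc, curvature);
  NumericMatrix out(nr, nc);
  for (size_t i = 0; i < m.size(); ++i) out[i] = -m[i];
  return out;
}
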