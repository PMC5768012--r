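#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e30;

// 1D squared-distance transform of a sampled function (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher 2012), grid positions i * step.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s = 0.0;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Euclidean distance (same units as spacing) from every voxel to the nearest
// TRUE voxel of a 3D mask. All-FALSE masks yield a large sentinel (>= 1e14).
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (fastest varying)
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  }
  // pass along axis 2
  for (int k = 0; k < n3; ++k) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }
  }
  // pass along axis 3
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * plane];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * plane] = d[k];
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// Trilinear interpolation of a 3D volume at continuous 0-based voxel
// coordinates; points outside [0, n-1] on any axis return `outside`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dims,
                          NumericVector xi, NumericVector yi,
                          NumericVector zi, double outside) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t np = xi.size();
  NumericVector out(np);
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = xi[p], y = yi[p], z = zi[p];
    if (!(x >= 0.0 && x <= n1 - 1.0 && y >= 0.0 && y <= n2 - 1.0 &&
          z >= 0.0 && z <= n3 - 1.0)) {
      out[p] = outside;
      continue;
    }
    int i0 = (int)std::floor(x); if (i0 > n1 - 2) i0 = n1 - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > n2 - 2) j0 = n2 - 2; if (j0 < 0) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > n3 - 2) k0 = n3 - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (n1 == 1) { i0 = 0; fx = 0.0; }
    if (n2 == 1) { j0 = 0; fy = 0.0; }
    if (n3 == 1) { k0 = 0; fz = 0.0; }
    R_xlen_t b000 = (R_xlen_t)k0 * plane + (R_xlen_t)j0 * n1 + i0;
    int di = (n1 > 1) ? 1 : 0;
    R_xlen_t dj = (n2 > 1) ? n1 : 0;
    R_xlen_t dk = (n3 > 1) ? plane : 0;
    double c00 = vol[b000] * (1 - fx) + vol[b000 + di] * fx;
    double c10 = vol[b000 + dj] * (1 - fx) + vol[b000 + dj + di] * fx;
    double c01 = vol[b000 + dk] * (1 - fx) + vol[b000 + dk + di] * fx;
    double c11 = vol[b000 + dk + dj] * (1 - fx) + vol[b000 + dk + dj + di] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Bilinear interpolation of a matrix at continuous 0-based coordinates.
// [[Rcpp::export]]
NumericVector cpp_interp2(NumericMatrix m, NumericVector xi,
                          NumericVector yi, double outside) {
  const int n1 = m.nrow(), n2 = m.ncol();
  const R_xlen_t np = xi.size();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = xi[p], y = yi[p];
    if (!(x >= 0.0 && x <= n1 - 1.0 && y >= 0.0 && y <= n2 - 1.0)) {
      out[p] = outside;
      continue;
    }
    int i0 = (int)std::floor(x); if (i0 > n1 - 2) i0 = n1 - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > n2 - 2) j0 = n2 - 2; if (j0 < 0) j0 = 0;
    double fx = x - i0, fy = y - j0;
    if (n1 == 1) { fx = 0.0; }
    if (n2 == 1) { fy = 0.0; }
    int di = (n1 > 1) ? 1 : 0, dj = (n2 > 1) ? 1 : 0;
    double c0 = m(i0, j0) * (1 - fx) + m(i0 + di, j0) * fx;
    double c1 = m(i0, j0 + dj) * (1 - fx) + m(i0 + di, j0 + dj) * fx;
    out[p] = c0 * (1 - fy) + c1 * fy;
  }
  return out;
}

// Separable 2D convolution with an odd-length kernel, zero padding.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep2(NumericMatrix m, NumericVector kern) {
  const int n1 = m.nrow(), n2 = m.ncol(), nk = kern.size();
  const int h = nk / 2;
  NumericMatrix tmp(n1, n2), out(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      int lo = std::max(0, i - h), hi = std::min(n1 - 1, i + h);
      for (int t = lo; t <= hi; ++t) acc += m(t, j) * kern[h + (i - t)];
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0;
      int lo = std::max(0, j - h), hi = std::min(n2 - 1, j + h);
      for (int t = lo; t <= hi; ++t) acc += tmp(i, t) * kern[h + (j - t)];
      out(i, j) = acc;
    }
  }
  return out;
}
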