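#include <Rcpp.h>
#include <vector>
#include <limits>

// Anisotropic squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher). Runs one axis at a time on the
// squared-distance field, so spacing can differ per axis. Sites with
// infinite f (no target anywhere on the line yet) are skipped; with
// z[0] = -inf the envelope loop cannot underflow.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  static thread_local std::vector<int> sites;
  sites.clear();
  for (int i = 0; i < n; ++i)
    if (f[i] < INF) sites.push_back(i);
  if (sites.empty()) {
    for (int i = 0; i < n; ++i) d[i] = INF;
    return;
  }
  const int m = (int)sites.size();
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  const double s2 = step * step;
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF;
  z[1] = INF;
  for (int idx = 1; idx < m; ++idx) {
    const int q = sites[idx];
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
          (2.0 * s2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
Rcpp::NumericVector edt_sq(Rcpp::LogicalVector target,
                           Rcpp::IntegerVector dim,
                           Rcpp::NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = target[i] ? 0.0 : INF;

  { // x pass
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) f[x] = g[base + x];
        dt1d(f, d, spacing[0]);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  { // y pass
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
        dt1d(f, d, spacing[1]);
        for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  { // z pass
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
        dt1d(f, d, spacing[2]);
        for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
      }
  }
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}
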