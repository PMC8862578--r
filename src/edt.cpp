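#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher, lower
// envelope of parabolas). Sample positions are i*h; f holds squared
// distances from an earlier pass.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from each voxel center to the nearest voxel
// center outside `mask`, with anisotropic spacing. The grid is padded by
// one background layer so that the exterior beyond the array edge counts
// as background. Off-mask voxels get 0.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim,
                    NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)px * py * pz, 0.0);
  // padded interior: INF where in-mask, 0 elsewhere (features = background)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t src = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        if (mask[src]) {
          size_t dst = (size_t)(i + 1) +
                       (size_t)px * ((j + 1) + (size_t)py * (k + 1));
          g[dst] = INF;
        }
      }

  // pass along x
  {
    std::vector<double> f(px), d(px);
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j) {
        size_t base = (size_t)px * (j + (size_t)py * k);
        for (int i = 0; i < px; ++i) f[i] = g[base + i];
        dt1d(f, d, px, spacing[0]);
        for (int i = 0; i < px; ++i) g[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(py), d(py);
    for (int k = 0; k < pz; ++k)
      for (int i = 0; i < px; ++i) {
        size_t base = (size_t)i + (size_t)px * py * (size_t)k;
        for (int j = 0; j < py; ++j) f[j] = g[base + (size_t)px * j];
        dt1d(f, d, py, spacing[1]);
        for (int j = 0; j < py; ++j) g[base + (size_t)px * j] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(pz), d(pz);
    for (int j = 0; j < py; ++j)
      for (int i = 0; i < px; ++i) {
        size_t base = (size_t)i + (size_t)px * j;
        for (int k = 0; k < pz; ++k)
          f[k] = g[base + (size_t)px * py * (size_t)k];
        dt1d(f, d, pz, spacing[2]);
        for (int k = 0; k < pz; ++k)
          g[base + (size_t)px * py * (size_t)k] = d[k];
      }
  }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t src = (size_t)(i + 1) +
                     (size_t)px * ((j + 1) + (size_t)py * (k + 1));
        size_t dst = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        out[dst] = std::sqrt(g[src]);
      }
  out.attr("dim") = dim;
  return out;
}
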