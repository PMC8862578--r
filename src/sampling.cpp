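#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Points outside [0, n-1] on any axis (beyond 1e-9 slack) yield NA.
// [[Rcpp::export(name = ".trilinear")]]
NumericVector trilinear(NumericVector vol, IntegerVector dim,
                        NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double eps = 1e-9;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < -eps || y < -eps || z < -eps ||
        x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) {
      out[p] = NA_REAL;
      continue;
    }
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
    if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
    if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = nx > 1 ? i0 + 1 : i0;
    int j1 = ny > 1 ? j0 + 1 : j0;
    int k1 = nz > 1 ? k0 + 1 : k0;
    if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
    #define V(i, j, k) vol[(size_t)(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-voxel lookup of an integer grid at continuous 0-based voxel
// coordinates; NA outside the grid.
// [[Rcpp::export(name = ".nn_lookup")]]
IntegerVector nn_lookup(IntegerVector vol, IntegerVector dim,
                        NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  IntegerVector out(n);
  const double eps = 1e-9;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < -0.5 - eps || y < -0.5 - eps || z < -0.5 - eps ||
        x > nx - 0.5 + eps || y > ny - 0.5 + eps || z > nz - 0.5 + eps) {
      out[p] = NA_INTEGER;
      continue;
    }
    int i = (int)std::lround(x), j = (int)std::lround(y),
        k = (int)std::lround(z);
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i > nx - 1) i = nx - 1;
    if (j > ny - 1) j = ny - 1;
    if (k > nz - 1) k = nz - 1;
    out[p] = vol[(size_t)i + (size_t)nx * (j + (size_t)ny * k)];
  }
  return out;
}
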