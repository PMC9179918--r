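#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance transform of a 3D grid, separable
// lower-envelope algorithm (Felzenszwalb & Huttenlocher 2012), one
// 1D pass per axis. Anisotropic voxel spacing is handled by weighting
// sample positions with the physical spacing of each axis.

static const double BIG = 1e20;

// In-place 1D squared distance transform of f (length n, samples at
// physical positions w*0, w*1, ..., w*(n-1)); result written to d.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      // abscissa (physical units) where parabolas p and q intersect
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w * (q - p));
      if (s <= z[k] && k > 0) {
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
    double x = w * q;
    while (z[k + 1] < x) ++k;
    double dx = x - w * v[k];
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3dSq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mask.size() != nvox) stop("mask length does not match dim");
  NumericVector out(nvox);
  // distance to nearest background (FALSE) voxel
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      edt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      edt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      edt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  // squared distances >= BIG/2 mean "no background voxel anywhere"
  for (R_xlen_t i = 0; i < nvox; ++i)
    if (out[i] >= BIG / 2) out[i] = R_PosInf;
  return out;
}
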