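#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Kaiser-Bessel interpolation kernels for the 3D gridding NUFFT.
//
// Coordinates arrive in oversampled-grid units, centred at zero; grids are
// stored in wrapped (DC-first) order so that index m on axis d lives at
// ((m % G) + G) % G.  The kernel is evaluated through a dense lookup table
// of exact Bessel values (computed in R) with linear interpolation; the
// table is sampled finely enough that the interpolation error is below the
// aliasing error of the kernel itself.

static inline double kb_lookup(double t, double halfwidth,
                               const double *table, int ntab) {
  double a = std::abs(t);
  if (a >= halfwidth) return 0.0;
  double u = a / halfwidth * (ntab - 1);
  int i = (int)u;
  if (i >= ntab - 1) return table[ntab - 1];
  double f = u - i;
  return table[i] * (1.0 - f) + table[i + 1] * f;
}

static inline int wrap(int m, int G) {
  int r = m % G;
  return r < 0 ? r + G : r;
}

// per-sample axis weights: fills idx[] (wrapped grid indices) and wt[]
static inline int axis_weights(double p, int G, double w,
                               const double *table, int ntab,
                               int *idx, double *wt) {
  double hw = w / 2.0;
  int lo = (int)std::ceil(p - hw);
  int hi = (int)std::floor(p + hw);
  int n = 0;
  for (int m = lo; m <= hi; ++m) {
    double v = kb_lookup(m - p, hw, table, ntab);
    if (v != 0.0) {
      idx[n] = wrap(m, G);
      wt[n] = v;
      ++n;
    }
  }
  return n;
}

// [[Rcpp::export(name = ".kbSpread3")]]
ComplexVector kbSpread3(NumericMatrix coords, ComplexVector vals,
                        IntegerVector gdim, double width,
                        NumericVector table) {
  const int M = coords.nrow();
  const int G1 = gdim[0], G2 = gdim[1], G3 = gdim[2];
  const int ntab = table.size();
  const double *tab = REAL(table);
  std::vector<std::complex<double> > out((size_t)G1 * G2 * G3,
                                         std::complex<double>(0.0, 0.0));
  int ix[32], iy[32], iz[32];
  double wx[32], wy[32], wz[32];
  for (int j = 0; j < M; ++j) {
    int nx = axis_weights(coords(j, 0), G1, width, tab, ntab, ix, wx);
    int ny = axis_weights(coords(j, 1), G2, width, tab, ntab, iy, wy);
    int nz = axis_weights(coords(j, 2), G3, width, tab, ntab, iz, wz);
    std::complex<double> v(vals[j].r, vals[j].i);
    for (int c = 0; c < nz; ++c) {
      size_t oz = (size_t)iz[c] * G2;
      std::complex<double> vz = v * wz[c];
      for (int b = 0; b < ny; ++b) {
        size_t oy = (oz + iy[b]) * G1;
        std::complex<double> vyz = vz * wy[b];
        for (int a = 0; a < nx; ++a)
          out[oy + ix[a]] += vyz * wx[a];
      }
    }
  }
  ComplexVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    res[i].r = out[i].real();
    res[i].i = out[i].imag();
  }
  res.attr("dim") = gdim;
  return res;
}

// [[Rcpp::export(name = ".kbInterp3")]]
ComplexVector kbInterp3(ComplexVector grid, NumericMatrix coords,
                        IntegerVector gdim, double width,
                        NumericVector table) {
  const int M = coords.nrow();
  const int G1 = gdim[0], G2 = gdim[1], G3 = gdim[2];
  const int ntab = table.size();
  const double *tab = REAL(table);
  const Rcomplex *g = COMPLEX(grid);
  ComplexVector res(M);
  int ix[32], iy[32], iz[32];
  double wx[32], wy[32], wz[32];
  for (int j = 0; j < M; ++j) {
    int nx = axis_weights(coords(j, 0), G1, width, tab, ntab, ix, wx);
    int ny = axis_weights(coords(j, 1), G2, width, tab, ntab, iy, wy);
    int nz = axis_weights(coords(j, 2), G3, width, tab, ntab, iz, wz);
    std::complex<double> acc(0.0, 0.0);
    for (int c = 0; c < nz; ++c) {
      size_t oz = (size_t)iz[c] * G2;
      for (int b = 0; b < ny; ++b) {
        size_t oy = (oz + iy[b]) * G1;
        double wyz = wz[c] * wy[b];
        for (int a = 0; a < nx; ++a) {
          const Rcomplex &q = g[oy + ix[a]];
          double w = wyz * wx[a];
          acc += std::complex<double>(q.r * w, q.i * w);
        }
      }
    }
    res[j].r = acc.real();
    res[j].i = acc.imag();
  }
  return res;
}

// Trilinear resampling of a 3D volume at arbitrary voxel coordinates
// (0-based, possibly fractional); out-of-field coordinates give zero.

// [[Rcpp::export(name = ".trilinear3")]]
NumericVector trilinear3(NumericVector vol, IntegerVector dim,
                         NumericMatrix coords) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int M = coords.nrow();
  const double *v = REAL(vol);
  NumericVector res(M);
  const double eps = 1e-9;
  for (int j = 0; j < M; ++j) {
    double x = coords(j, 0), y = coords(j, 1), z = coords(j, 2);
    // tolerate floating-point dust at the field-of-view boundary
    if (x > -eps && x < 0.0) x = 0.0;
    if (y > -eps && y < 0.0) y = 0.0;
    if (z > -eps && z < 0.0) z = 0.0;
    if (x > n1 - 1.0 && x < n1 - 1.0 + eps) x = n1 - 1.0;
    if (y > n2 - 1.0 && y < n2 - 1.0 + eps) y = n2 - 1.0;
    if (z > n3 - 1.0 && z < n3 - 1.0 + eps) z = n3 - 1.0;
    if (!(x >= 0.0 && x <= n1 - 1.0 && y >= 0.0 && y <= n2 - 1.0 &&
          z >= 0.0 && z <= n3 - 1.0)) {
      res[j] = 0.0;
      continue;
    }
    int x0 = (int)x, y0 = (int)y, z0 = (int)z;
    if (x0 == n1 - 1) x0--;
    if (y0 == n2 - 1) y0--;
    if (z0 == n3 - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    size_t i000 = (size_t)x0 + (size_t)n1 * (y0 + (size_t)n2 * z0);
    size_t dz = (size_t)n1 * n2;
    double c00 = v[i000] * (1 - fx) + v[i000 + 1] * fx;
    double c10 = v[i000 + n1] * (1 - fx) + v[i000 + n1 + 1] * fx;
    double c01 = v[i000 + dz] * (1 - fx) + v[i000 + dz + 1] * fx;
    double c11 = v[i000 + dz + n1] * (1 - fx) + v[i000 + dz + n1 + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    res[j] = c0 * (1 - fz) + c1 * fz;
  }
  return res;
}
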