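// Low-level kernels: im2col/col2im for 3D convolution (the conv, transposed
// conv and their gradients are all expressed through these two plus GEMM in
// R), and an exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope scan per axis).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// x: 4D array (nx, ny, nz, C) column-major. Returns (k3*C) x N matrix with
// row index dx + kx*(dy + ky*(dz + kz*c)) and column index the output voxel
// (x fastest). Out-of-bounds taps are zero (zero padding).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector kdim,
                         IntegerVector stride, IntegerVector pad) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], C = d[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = out_extent(nx, kx, sx, px);
  const int oy = out_extent(ny, ky, sy, py);
  const int oz = out_extent(nz, kz, sz, pz);
  const int N = ox * oy * oz;
  const int K3 = kx * ky * kz;
  NumericMatrix out(K3 * C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t volume = plane * nz;
  for (int czi = 0; czi < oz; ++czi) {
    for (int cyi = 0; cyi < oy; ++cyi) {
      for (int cxi = 0; cxi < ox; ++cxi) {
        const int col = cxi + ox * (cyi + oy * czi);
        double* colp = op + (R_xlen_t)col * (K3 * C);
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (R_xlen_t)c * volume;
          for (int dz = 0; dz < kz; ++dz) {
            const int iz = czi * sz - pz + dz;
            for (int dy = 0; dy < ky; ++dy) {
              const int iy = cyi * sy - py + dy;
              for (int dx = 0; dx < kx; ++dx) {
                const int ix = cxi * sx - px + dx;
                const int row = dx + kx * (dy + ky * (dz + kz * c));
                double v = 0.0;
                if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
                  v = xc[ix + nx * iy + plane * iz];
                colp[row] = v;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back into an array of shape
// in_shape = (nx, ny, nz, C).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector in_shape,
                         IntegerVector kdim, IntegerVector stride,
                         IntegerVector pad) {
  const int nx = in_shape[0], ny = in_shape[1], nz = in_shape[2], C = in_shape[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int ox = out_extent(nx, kx, sx, px);
  const int oy = out_extent(ny, ky, sy, py);
  const int oz = out_extent(nz, kz, sz, pz);
  const int K3 = kx * ky * kz;
  NumericVector out((R_xlen_t)nx * ny * nz * C);
  out.attr("dim") = in_shape;
  double* xp = out.begin();
  const double* op = cols.begin();
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t volume = plane * nz;
  for (int czi = 0; czi < oz; ++czi) {
    for (int cyi = 0; cyi < oy; ++cyi) {
      for (int cxi = 0; cxi < ox; ++cxi) {
        const int col = cxi + ox * (cyi + oy * czi);
        const double* colp = op + (R_xlen_t)col * (K3 * C);
        for (int c = 0; c < C; ++c) {
          double* xc = xp + (R_xlen_t)c * volume;
          for (int dz = 0; dz < kz; ++dz) {
            const int iz = czi * sz - pz + dz;
            if (iz < 0 || iz >= nz) continue;
            for (int dy = 0; dy < ky; ++dy) {
              const int iy = cyi * sy - py + dy;
              if (iy < 0 || iy >= ny) continue;
              for (int dx = 0; dx < kx; ++dx) {
                const int ix = cxi * sx - px + dx;
                if (ix < 0 || ix >= nx) continue;
                const int row = dx + kx * (dy + ky * (dz + kz * c));
                xc[ix + nx * iy + plane * iz] += colp[row];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// 1D squared-distance transform with sample spacing w (lower envelope of
// parabolas). f is modified in place through d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double w) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest voxel
// with mask != 0, on an anisotropic grid with the given spacing.
// [[Rcpp::export]]
NumericVector cpp_sedt(NumericVector mask, NumericVector spacing) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const double INF = 1e30;
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = d;
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = (mask[i] != 0.0) ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      double* row = out.begin() + nx * iy + plane * iz;
      f.assign(row, row + nx);
      dt1d(f, dd, v, z, spacing[0]);
      std::copy(dd.begin(), dd.begin() + nx, row);
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      double* base = out.begin() + ix + plane * iz;
      for (int iy = 0; iy < ny; ++iy) f[iy] = base[(R_xlen_t)nx * iy];
      std::vector<double> fv(f.begin(), f.begin() + ny);
      dt1d(fv, dd, v, z, spacing[1]);
      for (int iy = 0; iy < ny; ++iy) base[(R_xlen_t)nx * iy] = dd[iy];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      double* base = out.begin() + ix + (R_xlen_t)nx * iy;
      for (int iz = 0; iz < nz; ++iz) f[iz] = base[plane * iz];
      std::vector<double> fv(f.begin(), f.begin() + nz);
      dt1d(fv, dd, v, z, spacing[2]);
      for (int iz = 0; iz < nz; ++iz) base[plane * iz] = dd[iz];
    }
  return out;
}
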