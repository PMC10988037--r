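#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// Array layout throughout: column-major (nx, ny, nz, channels), matching R.
// idx = x + nx*(y + ny*(z + nz*c))

static inline R_xlen_t vox_index(int x, int y, int z, int nx, int ny, int nz) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Same-padded 3-D convolution with odd kernel k and dilation r.
// x: (nx,ny,nz,ci), w: (k,k,k,ci,co), bias: (co). Output (nx,ny,nz,co).
// Each output row is accumulated in an L1-resident buffer across all taps
// and input channels before being stored once.
// [[Rcpp::export]]
NumericVector cc_conv3d_fwd(NumericVector x, IntegerVector dims,
                            NumericVector w, int k, int r,
                            int cin, int cout, NumericVector bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nvox * cout);
  const int c = (k - 1) / 2;
  const double *xp = x.begin();
  double *op = out.begin();
  const double *wp = w.begin();
  std::vector<double> accbuf(nx);
  double * __restrict acc = accbuf.data();

  for (int co = 0; co < cout; ++co) {
    double *oc = op + nvox * co;
    const double b = bias[co];
    const double *wco = wp + (R_xlen_t)k * k * k * cin * co;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int xg = 0; xg < nx; ++xg) acc[xg] = b;
        for (int ci = 0; ci < cin; ++ci) {
          const double *xc = xp + nvox * ci;
          const double *wci = wco + (R_xlen_t)k * k * k * ci;
          for (int kz = 0; kz < k; ++kz) {
            const int zz = z + r * (kz - c);
            if (zz < 0 || zz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = y + r * (ky - c);
              if (yy < 0 || yy >= ny) continue;
              const double * __restrict xrow =
                xc + vox_index(0, yy, zz, nx, ny, nz);
              const double *wrow = wci + k * (ky + k * kz);
              for (int kx = 0; kx < k; ++kx) {
                const int dx = r * (kx - c);
                const int x0 = dx < 0 ? -dx : 0;
                const int x1 = nx - 1 - (dx > 0 ? dx : 0);
                const double wv = wrow[kx];
                const double * __restrict xs = xrow + dx;
                for (int xg = x0; xg <= x1; ++xg)
                  acc[xg] += wv * xs[xg];
              }
            }
          }
        }
        double * __restrict orow = oc + vox_index(0, y, z, nx, ny, nz);
        for (int xg = 0; xg < nx; ++xg) orow[xg] = acc[xg];
      }
    }
  }
  return out;
}

// Gradient of cc_conv3d_fwd w.r.t. the kernel weights.
// gw[kx,ky,kz,ci,co] = sum over valid voxels of x[p+d, ci] * gy[p, co].
// Row-major traversal keeps the gy row hot while all taps consume it.
// [[Rcpp::export]]
NumericVector cc_conv3d_bww(NumericVector x, NumericVector gy,
                            IntegerVector dims, int k, int r,
                            int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gw((R_xlen_t)k * k * k * cin * cout);
  const int c = (k - 1) / 2;
  const double *xp = x.begin(), *gp = gy.begin();
  double *wp = gw.begin();
  const R_xlen_t ntap = (R_xlen_t)k * k * k;
  std::vector<double> buf(ntap * cin);

  for (int co = 0; co < cout; ++co) {
    const double *gc = gp + nvox * co;
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        const double * __restrict grow = gc + vox_index(0, y, z, nx, ny, nz);
        for (int ci = 0; ci < cin; ++ci) {
          const double *xc = xp + nvox * ci;
          double *bci = buf.data() + ntap * ci;
          for (int kz = 0; kz < k; ++kz) {
            const int zz = z + r * (kz - c);
            if (zz < 0 || zz >= nz) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = y + r * (ky - c);
              if (yy < 0 || yy >= ny) continue;
              const double * __restrict xrow =
                xc + vox_index(0, yy, zz, nx, ny, nz);
              double *brow = bci + k * (ky + k * kz);
              for (int kx = 0; kx < k; ++kx) {
                const int dx = r * (kx - c);
                const int x0 = dx < 0 ? -dx : 0;
                const int x1 = nx - 1 - (dx > 0 ? dx : 0);
                const double * __restrict xs = xrow + dx;
                double acc = 0.0;
                for (int xg = x0; xg <= x1; ++xg)
                  acc += grow[xg] * xs[xg];
                brow[kx] += acc;
              }
            }
          }
        }
      }
    }
    double *wco = wp + ntap * cin * co;
    for (R_xlen_t i = 0; i < ntap * cin; ++i) wco[i] = buf[i];
  }
  return gw;
}

// Strided 2x2x2 downsampling convolution (stride 2, no padding).
// x: (nx,ny,nz,ci) with even spatial dims; out: (nx/2,ny/2,nz/2,co).
// [[Rcpp::export]]
NumericVector cc_down_fwd(NumericVector x, IntegerVector dims,
                          NumericVector w, int cin, int cout,
                          NumericVector bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector out(mvox * cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *op = out.begin();

  for (int co = 0; co < cout; ++co) {
    double *oc = op + mvox * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < mvox; ++i) oc[i] = b;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv =
              wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))];
            for (int z = 0; z < mz; ++z)
              for (int y = 0; y < my; ++y) {
                double * __restrict orow = oc + vox_index(0, y, z, mx, my, mz);
                const double * __restrict xrow =
                  xc + vox_index(dx, 2 * y + dy, 2 * z + dz, nx, ny, nz);
                for (int xg = 0; xg < mx; ++xg)
                  orow[xg] += wv * xrow[2 * xg];
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cc_down_bwx(NumericVector gy, IntegerVector dims,
                          NumericVector w, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector gx(nvox * cin);
  const double *gp = gy.begin(), *wp = w.begin();
  double *xp = gx.begin();

  for (int co = 0; co < cout; ++co) {
    const double *gc = gp + mvox * co;
    for (int ci = 0; ci < cin; ++ci) {
      double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv =
              wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))];
            for (int z = 0; z < mz; ++z)
              for (int y = 0; y < my; ++y) {
                const double * __restrict grow = gc + vox_index(0, y, z, mx, my, mz);
                double *xrow =
                  xc + vox_index(dx, 2 * y + dy, 2 * z + dz, nx, ny, nz);
                for (int xg = 0; xg < mx; ++xg)
                  xrow[2 * xg] += wv * grow[xg];
              }
          }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cc_down_bww(NumericVector x, NumericVector gy,
                          IntegerVector dims, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector gw((R_xlen_t)8 * cin * cout);
  const double *xp = x.begin(), *gp = gy.begin();
  double *wp = gw.begin();

  for (int co = 0; co < cout; ++co) {
    const double *gc = gp + mvox * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double acc = 0.0;
            for (int z = 0; z < mz; ++z)
              for (int y = 0; y < my; ++y) {
                const double * __restrict grow = gc + vox_index(0, y, z, mx, my, mz);
                const double * __restrict xrow =
                  xc + vox_index(dx, 2 * y + dy, 2 * z + dz, nx, ny, nz);
                for (int xg = 0; xg < mx; ++xg)
                  acc += grow[xg] * xrow[2 * xg];
              }
            wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))] = acc;
          }
    }
  }
  return gw;
}

// Transposed 2x2x2 stride-2 convolution (upsampling). x: (nx,ny,nz,ci);
// out: (2nx,2ny,2nz,co). Each output voxel receives exactly one input voxel.
// [[Rcpp::export]]
NumericVector cc_up_fwd(NumericVector x, IntegerVector dims,
                        NumericVector w, int cin, int cout,
                        NumericVector bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx * 2, my = ny * 2, mz = nz * 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector out(mvox * cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *op = out.begin();

  for (int co = 0; co < cout; ++co) {
    double *oc = op + mvox * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < mvox; ++i) oc[i] = b;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv =
              wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))];
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y) {
                const double * __restrict xrow = xc + vox_index(0, y, z, nx, ny, nz);
                double * __restrict orow =
                  oc + vox_index(dx, 2 * y + dy, 2 * z + dz, mx, my, mz);
                for (int xg = 0; xg < nx; ++xg)
                  orow[2 * xg] += wv * xrow[xg];
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cc_up_bwx(NumericVector gy, IntegerVector dims,
                        NumericVector w, int cin, int cout) {
  // dims are the dims of the *input* x
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx * 2, my = ny * 2, mz = nz * 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector gx(nvox * cin);
  const double *gp = gy.begin(), *wp = w.begin();
  double *xp = gx.begin();

  for (int co = 0; co < cout; ++co) {
    const double *gc = gp + mvox * co;
    for (int ci = 0; ci < cin; ++ci) {
      double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv =
              wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))];
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y) {
                double * __restrict xrow = xc + vox_index(0, y, z, nx, ny, nz);
                const double * __restrict grow =
                  gc + vox_index(dx, 2 * y + dy, 2 * z + dz, mx, my, mz);
                for (int xg = 0; xg < nx; ++xg)
                  xrow[xg] += wv * grow[2 * xg];
              }
          }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cc_up_bww(NumericVector x, NumericVector gy,
                        IntegerVector dims, int cin, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx * 2, my = ny * 2, mz = nz * 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gw((R_xlen_t)8 * cin * cout);
  const double *xp = x.begin(), *gp = gy.begin();
  double *wp = gw.begin();

  for (int co = 0; co < cout; ++co) {
    const double *gc = gp + (R_xlen_t)mx * my * mz * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = xp + nvox * ci;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double acc = 0.0;
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y) {
                const double * __restrict xrow = xc + vox_index(0, y, z, nx, ny, nz);
                const double * __restrict grow =
                  gc + vox_index(dx, 2 * y + dy, 2 * z + dz, mx, my, mz);
                for (int xg = 0; xg < nx; ++xg)
                  acc += xrow[xg] * grow[2 * xg];
              }
            wp[dx + 2 * (dy + 2 * (dz + 2 * (ci + (R_xlen_t)cin * co)))] = acc;
          }
    }
  }
  return gw;
}

// Per-axis interpolation table for factor-2 trilinear upsampling
// (voxel-center alignment: output o maps to input o/2 - 0.25, clamped).
static void up2_table(int n, std::vector<int> &i0, std::vector<int> &i1,
                      std::vector<double> &w0, std::vector<double> &w1) {
  const int m = 2 * n;
  i0.resize(m); i1.resize(m); w0.resize(m); w1.resize(m);
  for (int o = 0; o < m; ++o) {
    double src = 0.5 * o - 0.25;
    int lo = (int)std::floor(src);
    double t = src - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    i0[o] = lo; i1[o] = hi; w0[o] = 1.0 - t; w1[o] = t;
  }
}

// [[Rcpp::export]]
NumericVector cc_upsample2_fwd(NumericVector x, IntegerVector dims, int nc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector out(mvox * nc);
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw0, xw1, yw0, yw1, zw0, zw1;
  up2_table(nx, xi0, xi1, xw0, xw1);
  up2_table(ny, yi0, yi1, yw0, yw1);
  up2_table(nz, zi0, zi1, zw0, zw1);
  const double *xp = x.begin();
  double *op = out.begin();

  for (int c = 0; c < nc; ++c) {
    const double *xc = xp + nvox * c;
    double *oc = op + mvox * c;
    for (int z = 0; z < mz; ++z) {
      for (int y = 0; y < my; ++y) {
        const double *p00 = xc + vox_index(0, yi0[y], zi0[z], nx, ny, nz);
        const double *p10 = xc + vox_index(0, yi1[y], zi0[z], nx, ny, nz);
        const double *p01 = xc + vox_index(0, yi0[y], zi1[z], nx, ny, nz);
        const double *p11 = xc + vox_index(0, yi1[y], zi1[z], nx, ny, nz);
        const double a00 = yw0[y] * zw0[z], a10 = yw1[y] * zw0[z];
        const double a01 = yw0[y] * zw1[z], a11 = yw1[y] * zw1[z];
        double * __restrict orow = oc + vox_index(0, y, z, mx, my, mz);
        for (int xg = 0; xg < mx; ++xg) {
          const int l = xi0[xg], h = xi1[xg];
          const double v0 = a00 * p00[l] + a10 * p10[l] + a01 * p01[l] + a11 * p11[l];
          const double v1 = a00 * p00[h] + a10 * p10[h] + a01 * p01[h] + a11 * p11[h];
          orow[xg] = xw0[xg] * v0 + xw1[xg] * v1;
        }
      }
    }
  }
  return out;
}

// Adjoint of cc_upsample2_fwd (scatter-add with the same weights).
// [[Rcpp::export]]
NumericVector cc_upsample2_bwd(NumericVector gy, IntegerVector dims, int nc) {
  // dims are the dims of the *input* of the forward op
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = 2 * nx, my = 2 * ny, mz = 2 * nz;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t mvox = (R_xlen_t)mx * my * mz;
  NumericVector gx(nvox * nc);
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw0, xw1, yw0, yw1, zw0, zw1;
  up2_table(nx, xi0, xi1, xw0, xw1);
  up2_table(ny, yi0, yi1, yw0, yw1);
  up2_table(nz, zi0, zi1, zw0, zw1);
  const double *gp = gy.begin();
  double *xp = gx.begin();

  for (int c = 0; c < nc; ++c) {
    double *xc = xp + nvox * c;
    const double *gc = gp + mvox * c;
    for (int z = 0; z < mz; ++z) {
      for (int y = 0; y < my; ++y) {
        double *p00 = xc + vox_index(0, yi0[y], zi0[z], nx, ny, nz);
        double *p10 = xc + vox_index(0, yi1[y], zi0[z], nx, ny, nz);
        double *p01 = xc + vox_index(0, yi0[y], zi1[z], nx, ny, nz);
        double *p11 = xc + vox_index(0, yi1[y], zi1[z], nx, ny, nz);
        const double a00 = yw0[y] * zw0[z], a10 = yw1[y] * zw0[z];
        const double a01 = yw0[y] * zw1[z], a11 = yw1[y] * zw1[z];
        const double * __restrict grow = gc + vox_index(0, y, z, mx, my, mz);
        for (int xg = 0; xg < mx; ++xg) {
          const int l = xi0[xg], h = xi1[xg];
          const double g0 = grow[xg] * xw0[xg], g1 = grow[xg] * xw1[xg];
          p00[l] += a00 * g0; p10[l] += a10 * g0; p01[l] += a01 * g0; p11[l] += a11 * g0;
          p00[h] += a00 * g1; p10[h] += a10 * g1; p01[h] += a01 * g1; p11[h] += a11 * g1;
        }
      }
    }
  }
  return gx;
}

// Rasterize capsules (finite tube segments with hemispherical caps) onto a
// voxel grid. segs: n x 7 matrix, rows (x0,y0,z0,x1,y1,z1,radius) in mm.
// Voxel centers sit at (i + 0.5) * spacing. A voxel is foreground iff its
// center lies within `radius` of the nearest segment axis.
// [[Rcpp::export]]
IntegerVector cc_rasterize(NumericMatrix segs, IntegerVector dims,
                           NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  int *op = out.begin();

  for (int s = 0; s < segs.nrow(); ++s) {
    const double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    const double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    const double rad = segs(s, 6);
    const double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double len2 = ux * ux + uy * uy + uz * uz;
    // bounding box in voxel indices, inflated by the radius
    const double lox = std::min(ax, bx) - rad, hix = std::max(ax, bx) + rad;
    const double loy = std::min(ay, by) - rad, hiy = std::max(ay, by) + rad;
    const double loz = std::min(az, bz) - rad, hiz = std::max(az, bz) + rad;
    int x0 = std::max(0, (int)std::floor(lox / sx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil(hix / sx - 0.5));
    int y0 = std::max(0, (int)std::floor(loy / sy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil(hiy / sy - 0.5));
    int z0 = std::max(0, (int)std::floor(loz / sz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil(hiz / sz - 0.5));
    const double r2 = rad * rad;
    for (int z = z0; z <= z1; ++z) {
      const double pz = (z + 0.5) * sz;
      for (int y = y0; y <= y1; ++y) {
        const double py = (y + 0.5) * sy;
        for (int x = x0; x <= x1; ++x) {
          const double px = (x + 0.5) * sx;
          double t = 0.0;
          if (len2 > 0.0) {
            t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / len2;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
          }
          const double qx = ax + t * ux - px;
          const double qy = ay + t * uy - py;
          const double qz = az + t * uz - pz;
          if (qx * qx + qy * qy + qz * qz <= r2)
            op[vox_index(x, y, z, nx, ny, nz)] = 1;
        }
      }
    }
  }
  return out;
}

// 3-D connected-component labeling by flood fill.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cc_label3d(IntegerVector mask, IntegerVector dims,
                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(nvox);
  const int *mp = mask.begin();
  int *lp = labels.begin();

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int noff = (int)offx.size();

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t seed = 0; seed < nvox; ++seed) {
    if (mp[seed] == 0 || lp[seed] != 0) continue;
    ++next_label;
    lp[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int o = 0; o < noff; ++o) {
        const int xx = x + offx[o], yy = y + offy[o], zz = z + offz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t ni = vox_index(xx, yy, zz, nx, ny, nz);
        if (mp[ni] != 0 && lp[ni] == 0) {
          lp[ni] = next_label;
          stack.push_back(ni);
        }
      }
    }
  }
  return labels;
}
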