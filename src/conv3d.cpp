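#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution kernels for volumetric networks.
// Array layouts (R column-major):
//   x    : (nx, ny, nz, Cin)
//   w    : (kx, ky, kz, Cin, Cout)
//   out  : (ox, oy, oz, Cout)
// pad_mode: 0 = zero padding, 1 = replicate (clamped index) padding.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad, int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci_n = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co_n = wd[4];
  const int ox = out_size(nx, kx, stride, pad);
  const int oy = out_size(ny, ky, stride, pad);
  const int oz = out_size(nz, kz, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1)
    stop("convolution output would be empty: input volume too small for this architecture");
  NumericVector out(ox * (R_xlen_t)oy * oz * co_n);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co_n);
  const double *X = x.begin(), *W = w.begin(), *B = b.begin();
  double *O = out.begin();

  for (int co = 0; co < co_n; ++co) {
    for (int z = 0; z < oz; ++z) {
      for (int y = 0; y < oy; ++y) {
        for (int xo = 0; xo < ox; ++xo) {
          double acc = B[co];
          for (int ci = 0; ci < ci_n; ++ci) {
            for (int c = 0; c < kz; ++c) {
              int iz = z * stride - pad + c;
              if (pad_mode == 1) iz = clampi(iz, 0, nz - 1);
              else if (iz < 0 || iz >= nz) continue;
              for (int bk = 0; bk < ky; ++bk) {
                int iy = y * stride - pad + bk;
                if (pad_mode == 1) iy = clampi(iy, 0, ny - 1);
                else if (iy < 0 || iy >= ny) continue;
                for (int a = 0; a < kx; ++a) {
                  int ix = xo * stride - pad + a;
                  if (pad_mode == 1) ix = clampi(ix, 0, nx - 1);
                  else if (ix < 0 || ix >= nx) continue;
                  acc += X[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * (iz + (R_xlen_t)nz * ci))] *
                         W[a + (R_xlen_t)kx * (bk + (R_xlen_t)ky * (c + (R_xlen_t)kz * (ci + (R_xlen_t)ci_n * co)))];
                }
              }
            }
          }
          O[xo + (R_xlen_t)ox * (y + (R_xlen_t)oy * (z + (R_xlen_t)oz * co))] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
               int stride, int pad, int pad_mode) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci_n = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co_n = wd[4];
  const int ox = gd[0], oy = gd[1], oz = gd[2];
  NumericVector gx(x.size()), gw(w.size()), gb(co_n);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *X = x.begin(), *W = w.begin(), *G = gout.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();

  for (int co = 0; co < co_n; ++co) {
    for (int z = 0; z < oz; ++z) {
      for (int y = 0; y < oy; ++y) {
        for (int xo = 0; xo < ox; ++xo) {
          const double g = G[xo + (R_xlen_t)ox * (y + (R_xlen_t)oy * (z + (R_xlen_t)oz * co))];
          if (g == 0.0) continue;
          GB[co] += g;
          for (int ci = 0; ci < ci_n; ++ci) {
            for (int c = 0; c < kz; ++c) {
              int iz = z * stride - pad + c;
              if (pad_mode == 1) iz = clampi(iz, 0, nz - 1);
              else if (iz < 0 || iz >= nz) continue;
              for (int bk = 0; bk < ky; ++bk) {
                int iy = y * stride - pad + bk;
                if (pad_mode == 1) iy = clampi(iy, 0, ny - 1);
                else if (iy < 0 || iy >= ny) continue;
                for (int a = 0; a < kx; ++a) {
                  int ix = xo * stride - pad + a;
                  if (pad_mode == 1) ix = clampi(ix, 0, nx - 1);
                  else if (ix < 0 || ix >= nx) continue;
                  const R_xlen_t xi = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * (iz + (R_xlen_t)nz * ci));
                  const R_xlen_t wi = a + (R_xlen_t)kx * (bk + (R_xlen_t)ky * (c + (R_xlen_t)kz * (ci + (R_xlen_t)ci_n * co)));
                  GX[xi] += W[wi] * g;
                  GW[wi] += X[xi] * g;
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed (fractionally strided) 3D convolution.
//   x : (nx, ny, nz, Cin), w : (kx, ky, kz, Cin, Cout)
//   out size per axis: (n - 1) * stride + k - 2 * pad + out_pad

// [[Rcpp::export(name = ".convt3d_fw")]]
NumericVector convt3d_fw(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int out_pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci_n = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co_n = wd[4];
  const int ox = (nx - 1) * stride + kx - 2 * pad + out_pad;
  const int oy = (ny - 1) * stride + ky - 2 * pad + out_pad;
  const int oz = (nz - 1) * stride + kz - 2 * pad + out_pad;
  NumericVector out(ox * (R_xlen_t)oy * oz * co_n);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co_n);
  const double *X = x.begin(), *W = w.begin(), *B = b.begin();
  double *O = out.begin();
  for (int co = 0; co < co_n; ++co) {
    const R_xlen_t base = (R_xlen_t)ox * oy * oz * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) O[base + i] = B[co];
  }
  for (int ci = 0; ci < ci_n; ++ci) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int xi = 0; xi < nx; ++xi) {
          const double v = X[xi + (R_xlen_t)nx * (y + (R_xlen_t)ny * (z + (R_xlen_t)nz * ci))];
          if (v == 0.0) continue;
          for (int co = 0; co < co_n; ++co) {
            for (int c = 0; c < kz; ++c) {
              const int ozp = z * stride + c - pad;
              if (ozp < 0 || ozp >= oz) continue;
              for (int bk = 0; bk < ky; ++bk) {
                const int oyp = y * stride + bk - pad;
                if (oyp < 0 || oyp >= oy) continue;
                for (int a = 0; a < kx; ++a) {
                  const int oxp = xi * stride + a - pad;
                  if (oxp < 0 || oxp >= ox) continue;
                  O[oxp + (R_xlen_t)ox * (oyp + (R_xlen_t)oy * (ozp + (R_xlen_t)oz * co))] +=
                    v * W[a + (R_xlen_t)kx * (bk + (R_xlen_t)ky * (c + (R_xlen_t)kz * (ci + (R_xlen_t)ci_n * co)))];
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".convt3d_bw")]]
List convt3d_bw(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci_n = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co_n = wd[4];
  const int ox = gd[0], oy = gd[1], oz = gd[2];
  NumericVector gx(x.size()), gw(w.size()), gb(co_n);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *X = x.begin(), *W = w.begin(), *G = gout.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();

  for (int co = 0; co < co_n; ++co) {
    const R_xlen_t base = (R_xlen_t)ox * oy * oz * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) GB[co] += G[base + i];
  }
  for (int ci = 0; ci < ci_n; ++ci) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int xi = 0; xi < nx; ++xi) {
          const R_xlen_t xidx = xi + (R_xlen_t)nx * (y + (R_xlen_t)ny * (z + (R_xlen_t)nz * ci));
          const double xv = X[xidx];
          double acc = 0.0;
          for (int co = 0; co < co_n; ++co) {
            for (int c = 0; c < kz; ++c) {
              const int ozp = z * stride + c - pad;
              if (ozp < 0 || ozp >= oz) continue;
              for (int bk = 0; bk < ky; ++bk) {
                const int oyp = y * stride + bk - pad;
                if (oyp < 0 || oyp >= oy) continue;
                for (int a = 0; a < kx; ++a) {
                  const int oxp = xi * stride + a - pad;
                  if (oxp < 0 || oxp >= ox) continue;
                  const double g = G[oxp + (R_xlen_t)ox * (oyp + (R_xlen_t)oy * (ozp + (R_xlen_t)oz * co))];
                  const R_xlen_t wi = a + (R_xlen_t)kx * (bk + (R_xlen_t)ky * (c + (R_xlen_t)kz * (ci + (R_xlen_t)ci_n * co)));
                  acc += W[wi] * g;
                  GW[wi] += xv * g;
                }
              }
            }
          }
          GX[xidx] = acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
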