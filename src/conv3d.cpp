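// Direct 3D convolution kernels on column-major (x, y, z, channel)
// arrays.  Each kernel tap contributes a streaming AXPY over the valid
// output region, so the inner loop is contiguous along the x axis; at the
// patch sizes this package trains on, whole feature maps fit in cache and
// the loops run near ALU speed without any lowering matrix.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_len(int d, int k, int stride, int pad, int dil) {
  return (d + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// valid output range [lo, hi) for one axis and one kernel tap:
// 0 <= o*stride - pad + dil*kk <= D-1
static inline void tap_range(int D, int o, int stride, int pad, int dil,
                             int kk, int &lo, int &hi) {
  int off = dil * kk - pad;
  lo = off < 0 ? (-off + stride - 1) / stride : 0;
  int last = (D - 1 - off) / stride;  // off <= D-1 guaranteed by caller
  hi = last + 1;
  if (hi > o) hi = o;
  if (lo > hi) lo = hi;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 5) stop("bad array ranks");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("channel mismatch");
  const int o1 = out_len(D1, k, stride, pad, dil);
  const int o2 = out_len(D2, k, stride, pad, dil);
  const int o3 = out_len(D3, k, stride, pad, dil);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("kernel does not fit inside input");
  const R_xlen_t No = (R_xlen_t)o1 * o2 * o3;
  NumericVector y(No * Cout);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, Cout);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w), *bp = REAL(b);
  for (int co = 0; co < Cout; ++co) {
    double *yc = yp + (R_xlen_t)co * No;
    for (R_xlen_t i = 0; i < No; ++i) yc[i] = bp[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + (R_xlen_t)ci * D1 * D2 * D3;
      for (int k3 = 0; k3 < k; ++k3) {
        int z0, z1; tap_range(D3, o3, stride, pad, dil, k3, z0, z1);
        for (int k2 = 0; k2 < k; ++k2) {
          int y0, y1; tap_range(D2, o2, stride, pad, dil, k2, y0, y1);
          for (int k1 = 0; k1 < k; ++k1) {
            int x0, x1; tap_range(D1, o1, stride, pad, dil, k1, x0, x1);
            const double wv =
              wp[k1 + k * (k2 + k * (k3 + k * (ci + (R_xlen_t)Cin * co)))];
            if (wv == 0.0 || x0 >= x1) continue;
            const int offx = dil * k1 - pad;
            for (int z = z0; z < z1; ++z) {
              const int i3 = z * stride - pad + dil * k3;
              for (int yy = y0; yy < y1; ++yy) {
                const int i2 = yy * stride - pad + dil * k2;
                const double *__restrict__ xr =
                  xc + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3) + offx;
                double *__restrict__ yr = yc + (R_xlen_t)o1 * (yy + (R_xlen_t)o2 * z);
                if (stride == 1) {
                  for (int xx = x0; xx < x1; ++xx)
                    yr[xx] += wv * xr[xx];
                } else {
                  for (int xx = x0; xx < x1; ++xx)
                    yr[xx] += wv * xr[(R_xlen_t)xx * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// Gradients of conv3d_fwd with respect to input, weights and bias.
// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  const int o1 = out_len(D1, k, stride, pad, dil);
  const int o2 = out_len(D2, k, stride, pad, dil);
  const int o3 = out_len(D3, k, stride, pad, dil);
  const R_xlen_t No = (R_xlen_t)o1 * o2 * o3;
  NumericVector gx((R_xlen_t)D1 * D2 * D3 * Cin);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  double *gxp = REAL(gx), *gwp = REAL(gw), *gbp = REAL(gb);
  const double *xp = REAL(x), *wp = REAL(w), *gp = REAL(gy);
  for (int co = 0; co < Cout; ++co) {
    const double *gc = gp + (R_xlen_t)co * No;
    double s = 0.0;
    for (R_xlen_t i = 0; i < No; ++i) s += gc[i];
    gbp[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xp + (R_xlen_t)ci * D1 * D2 * D3;
      double *gxc = gxp + (R_xlen_t)ci * D1 * D2 * D3;
      for (int k3 = 0; k3 < k; ++k3) {
        int z0, z1; tap_range(D3, o3, stride, pad, dil, k3, z0, z1);
        for (int k2 = 0; k2 < k; ++k2) {
          int y0, y1; tap_range(D2, o2, stride, pad, dil, k2, y0, y1);
          for (int k1 = 0; k1 < k; ++k1) {
            int x0, x1; tap_range(D1, o1, stride, pad, dil, k1, x0, x1);
            if (x0 >= x1) continue;
            const R_xlen_t wi =
              k1 + k * (k2 + k * (k3 + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)));
            const double wv = wp[wi];
            const int offx = dil * k1 - pad;
            double acc = 0.0;
            for (int z = z0; z < z1; ++z) {
              const int i3 = z * stride - pad + dil * k3;
              for (int yy = y0; yy < y1; ++yy) {
                const int i2 = yy * stride - pad + dil * k2;
                const double *__restrict__ xr =
                  xc + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3) + offx;
                double *__restrict__ gxr =
                  gxc + (R_xlen_t)D1 * (i2 + (R_xlen_t)D2 * i3) + offx;
                const double *__restrict__ gr = gc + (R_xlen_t)o1 * (yy + (R_xlen_t)o2 * z);
                if (stride == 1) {
                  for (int xx = x0; xx < x1; ++xx) {
                    acc += gr[xx] * xr[xx];
                    gxr[xx] += wv * gr[xx];
                  }
                } else {
                  for (int xx = x0; xx < x1; ++xx) {
                    acc += gr[xx] * xr[(R_xlen_t)xx * stride];
                    gxr[(R_xlen_t)xx * stride] += wv * gr[xx];
                  }
                }
              }
            }
            gwp[wi] = acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}


// ---------------------------------------------------------------------
// Hot inner loops, isolated so they can carry stronger optimization and
// runtime ISA dispatch than the compiler's default flags (the surrounding
// build targets a lowest-common-denominator x86-64; these clones pick
// AVX2+FMA at load time when the CPU supports it).

#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("default", "avx2,fma"), \
  optimize("O3", "tree-vectorize", "associative-math", "no-signed-zeros", \
           "no-trapping-math", "no-math-errno")))
#else
#define HOT_CLONES
#endif

HOT_CLONES static void axpy_run(double *__restrict__ y,
                                const double *__restrict__ x,
                                const double w, const R_xlen_t n) {
  for (R_xlen_t i = 0; i < n; ++i) y[i] += w * x[i];
}

HOT_CLONES static double bwd_tap_run(double *__restrict__ gx,
                                     const double *__restrict__ x,
                                     const double *__restrict__ g,
                                     const double w, const R_xlen_t n) {
  double acc = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    acc += g[i] * x[i];
    gx[i] += w * g[i];
  }
  return acc;
}

// ---------------------------------------------------------------------
// Fast path for stride-1 same-padding convolutions (pad = dil*(k-1)/2):
// input and output grids coincide, so after zero-padding all three axes
// by `pad`, every kernel tap reduces to one long AXPY at a constant flat
// offset.  Padding regions absorb the row wrap-around and are discarded.

static void pad3(const double *x, double *xp, int D1, int D2, int D3,
                 int C, int p) {
  const int P1 = D1 + 2 * p, P2 = D2 + 2 * p, P3 = D3 + 2 * p;
  const R_xlen_t M = (R_xlen_t)P1 * P2 * P3;
  std::fill(xp, xp + M * C, 0.0);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < D3; ++z)
      for (int y = 0; y < D2; ++y) {
        const double *src = x + (R_xlen_t)D1 * (y + (R_xlen_t)D2 *
                            (z + (R_xlen_t)D3 * c));
        double *dst = xp + p + (R_xlen_t)P1 * ((y + p) + (R_xlen_t)P2 *
                      ((z + p) + (R_xlen_t)P3 * c));
        std::copy(src, src + D1, dst);
      }
}

static void unpad3(const double *xp, double *x, int D1, int D2, int D3,
                   int C, int p) {
  const int P1 = D1 + 2 * p, P2 = D2 + 2 * p, P3 = D3 + 2 * p;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < D3; ++z)
      for (int y = 0; y < D2; ++y) {
        const double *src = xp + p + (R_xlen_t)P1 * ((y + p) +
                            (R_xlen_t)P2 * ((z + p) + (R_xlen_t)P3 * c));
        double *dst = x + (R_xlen_t)D1 * (y + (R_xlen_t)D2 *
                      (z + (R_xlen_t)D3 * c));
        std::copy(src, src + D1, dst);
      }
}

// 4x4 channel-tiled tap loops: each pass over the padded volume serves a
// 4x4 block of (cin, cout) pairs, quartering memory traffic relative to
// one AXPY per channel pair.  Used when both channel counts are
// multiples of 4 (all interior layers); other layers take the generic
// per-pair path.

HOT_CLONES static void fwd_tap4(double *__restrict__ y0,
                                double *__restrict__ y1,
                                double *__restrict__ y2,
                                double *__restrict__ y3,
                                const double *__restrict__ x0,
                                const double *__restrict__ x1,
                                const double *__restrict__ x2,
                                const double *__restrict__ x3,
                                const double *wv, const R_xlen_t n) {
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = x0[i], b = x1[i], c = x2[i], d = x3[i];
    y0[i] += wv[0] * a + wv[1] * b + wv[2] * c + wv[3] * d;
    y1[i] += wv[4] * a + wv[5] * b + wv[6] * c + wv[7] * d;
    y2[i] += wv[8] * a + wv[9] * b + wv[10] * c + wv[11] * d;
    y3[i] += wv[12] * a + wv[13] * b + wv[14] * c + wv[15] * d;
  }
}

HOT_CLONES static void bwd_tap4(double *__restrict__ gx0,
                                double *__restrict__ gx1,
                                double *__restrict__ gx2,
                                double *__restrict__ gx3,
                                const double *__restrict__ x0,
                                const double *__restrict__ x1,
                                const double *__restrict__ x2,
                                const double *__restrict__ x3,
                                const double *__restrict__ g0,
                                const double *__restrict__ g1,
                                const double *__restrict__ g2,
                                const double *__restrict__ g3,
                                const double *wv, double *acc,
                                const R_xlen_t n) {
  double a00 = 0, a01 = 0, a02 = 0, a03 = 0, a10 = 0, a11 = 0, a12 = 0,
         a13 = 0, a20 = 0, a21 = 0, a22 = 0, a23 = 0, a30 = 0, a31 = 0,
         a32 = 0, a33 = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double ga = g0[i], gb = g1[i], gc = g2[i], gd = g3[i];
    const double xa = x0[i], xb = x1[i], xc_ = x2[i], xd = x3[i];
    a00 += ga * xa; a01 += gb * xa; a02 += gc * xa; a03 += gd * xa;
    a10 += ga * xb; a11 += gb * xb; a12 += gc * xb; a13 += gd * xb;
    a20 += ga * xc_; a21 += gb * xc_; a22 += gc * xc_; a23 += gd * xc_;
    a30 += ga * xd; a31 += gb * xd; a32 += gc * xd; a33 += gd * xd;
    gx0[i] += wv[0] * ga + wv[4] * gb + wv[8] * gc + wv[12] * gd;
    gx1[i] += wv[1] * ga + wv[5] * gb + wv[9] * gc + wv[13] * gd;
    gx2[i] += wv[2] * ga + wv[6] * gb + wv[10] * gc + wv[14] * gd;
    gx3[i] += wv[3] * ga + wv[7] * gb + wv[11] * gc + wv[15] * gd;
  }
  acc[0] += a00; acc[1] += a01; acc[2] += a02; acc[3] += a03;
  acc[4] += a10; acc[5] += a11; acc[6] += a12; acc[7] += a13;
  acc[8] += a20; acc[9] += a21; acc[10] += a22; acc[11] += a23;
  acc[12] += a30; acc[13] += a31; acc[14] += a32; acc[15] += a33;
}

// [[Rcpp::export(name = ".conv3d_fwd_same")]]
NumericVector conv3d_fwd_same(NumericVector x, NumericVector w,
                              NumericVector b, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("channel mismatch");
  const int p = dil * (k - 1) / 2;
  const int P1 = D1 + 2 * p, P2 = D2 + 2 * p, P3 = D3 + 2 * p;
  const R_xlen_t M = (R_xlen_t)P1 * P2 * P3;
  std::vector<double> xpad((size_t)M * Cin);
  std::vector<double> ypad((size_t)M * Cout, 0.0);
  pad3(REAL(x), xpad.data(), D1, D2, D3, Cin, p);
  const double *wp = REAL(w);
  const bool tiled = (Cin % 4 == 0) && (Cout % 4 == 0);
  if (tiled) {
    for (int co = 0; co < Cout; co += 4)
      for (int ci = 0; ci < Cin; ci += 4)
        for (int k3 = 0; k3 < k; ++k3)
          for (int k2 = 0; k2 < k; ++k2)
            for (int k1 = 0; k1 < k; ++k1) {
              const R_xlen_t off = (dil * k1 - p) +
                (R_xlen_t)P1 * ((dil * k2 - p) +
                (R_xlen_t)P2 * (dil * k3 - p));
              const R_xlen_t lo = off < 0 ? -off : 0;
              const R_xlen_t hi = off > 0 ? M - off : M;
              double wv[16];
              for (int j = 0; j < 4; ++j)
                for (int i = 0; i < 4; ++i)
                  wv[4 * j + i] = wp[k1 + k * (k2 + k * (k3 + k *
                    ((ci + i) + (R_xlen_t)Cin * (co + j))))];
              double *yb = ypad.data() + (R_xlen_t)co * M + lo;
              const double *xb = xpad.data() + (R_xlen_t)ci * M + off + lo;
              fwd_tap4(yb, yb + M, yb + 2 * M, yb + 3 * M,
                       xb, xb + M, xb + 2 * M, xb + 3 * M, wv, hi - lo);
            }
  } else {
    for (int co = 0; co < Cout; ++co) {
      double *__restrict__ yc = ypad.data() + (R_xlen_t)co * M;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xc = xpad.data() + (R_xlen_t)ci * M;
        for (int k3 = 0; k3 < k; ++k3)
          for (int k2 = 0; k2 < k; ++k2)
            for (int k1 = 0; k1 < k; ++k1) {
              const double wv = wp[k1 + k * (k2 + k * (k3 + k *
                                (ci + (R_xlen_t)Cin * co)))];
              if (wv == 0.0) continue;
              const R_xlen_t off = (dil * k1 - p) +
                (R_xlen_t)P1 * ((dil * k2 - p) +
                (R_xlen_t)P2 * (dil * k3 - p));
              const R_xlen_t lo = off < 0 ? -off : 0;
              const R_xlen_t hi = off > 0 ? M - off : M;
              axpy_run(yc + lo, xc + off + lo, wv, hi - lo);
            }
      }
    }
  }
  NumericVector y((R_xlen_t)D1 * D2 * D3 * Cout);
  y.attr("dim") = IntegerVector::create(D1, D2, D3, Cout);
  unpad3(ypad.data(), REAL(y), D1, D2, D3, Cout, p);
  double *yp = REAL(y);
  const double *bp = REAL(b);
  const R_xlen_t N = (R_xlen_t)D1 * D2 * D3;
  for (int co = 0; co < Cout; ++co) {
    double *yc = yp + (R_xlen_t)co * N;
    const double bv = bp[co];
    for (R_xlen_t i = 0; i < N; ++i) yc[i] += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd_same")]]
List conv3d_bwd_same(NumericVector x, NumericVector w, NumericVector gy,
                     int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  const int p = dil * (k - 1) / 2;
  const int P1 = D1 + 2 * p, P2 = D2 + 2 * p, P3 = D3 + 2 * p;
  const R_xlen_t M = (R_xlen_t)P1 * P2 * P3;
  const R_xlen_t N = (R_xlen_t)D1 * D2 * D3;
  std::vector<double> xpad((size_t)M * Cin);
  std::vector<double> gypad((size_t)M * Cout);
  std::vector<double> gxpad((size_t)M * Cin, 0.0);
  pad3(REAL(x), xpad.data(), D1, D2, D3, Cin, p);
  pad3(REAL(gy), gypad.data(), D1, D2, D3, Cout, p);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  double *gwp = REAL(gw), *gbp = REAL(gb);
  const double *wp = REAL(w), *gp = REAL(gy);
  for (int co = 0; co < Cout; ++co) {
    const double *gyc = gypad.data() + (R_xlen_t)co * M;
    const double *gu = gp + (R_xlen_t)co * N;
    double s = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) s += gu[i];
    gbp[co] = s;
    if ((Cin % 4 == 0) && (Cout % 4 == 0)) continue;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = xpad.data() + (R_xlen_t)ci * M;
      double *gxc = gxpad.data() + (R_xlen_t)ci * M;
      for (int k3 = 0; k3 < k; ++k3)
        for (int k2 = 0; k2 < k; ++k2)
          for (int k1 = 0; k1 < k; ++k1) {
            const R_xlen_t wi = k1 + k * (k2 + k * (k3 + (R_xlen_t)k *
                                (ci + (R_xlen_t)Cin * co)));
            const double wv = wp[wi];
            const R_xlen_t off = (dil * k1 - p) +
              (R_xlen_t)P1 * ((dil * k2 - p) +
              (R_xlen_t)P2 * (dil * k3 - p));
            const R_xlen_t lo = off < 0 ? -off : 0;
            const R_xlen_t hi = off > 0 ? M - off : M;
            gwp[wi] = bwd_tap_run(gxc + off + lo, xc + off + lo,
                                  gyc + lo, wv, hi - lo);
          }
    }
  }
  if ((Cin % 4 == 0) && (Cout % 4 == 0)) {
    for (int co = 0; co < Cout; co += 4)
      for (int ci = 0; ci < Cin; ci += 4)
        for (int k3 = 0; k3 < k; ++k3)
          for (int k2 = 0; k2 < k; ++k2)
            for (int k1 = 0; k1 < k; ++k1) {
              const R_xlen_t off = (dil * k1 - p) +
                (R_xlen_t)P1 * ((dil * k2 - p) +
                (R_xlen_t)P2 * (dil * k3 - p));
              const R_xlen_t lo = off < 0 ? -off : 0;
              const R_xlen_t hi = off > 0 ? M - off : M;
              double wv[16], acc[16];
              for (int j = 0; j < 4; ++j)
                for (int i = 0; i < 4; ++i) {
                  wv[4 * j + i] = wp[k1 + k * (k2 + k * (k3 + (R_xlen_t)k *
                    ((ci + i) + (R_xlen_t)Cin * (co + j))))];
                  acc[4 * i + j] = 0.0;
                }
              double *gxb = gxpad.data() + (R_xlen_t)ci * M + off + lo;
              const double *xb = xpad.data() + (R_xlen_t)ci * M + off + lo;
              const double *gb_ = gypad.data() + (R_xlen_t)co * M + lo;
              bwd_tap4(gxb, gxb + M, gxb + 2 * M, gxb + 3 * M,
                       xb, xb + M, xb + 2 * M, xb + 3 * M,
                       gb_, gb_ + M, gb_ + 2 * M, gb_ + 3 * M,
                       wv, acc, hi - lo);
              for (int i = 0; i < 4; ++i)
                for (int j = 0; j < 4; ++j)
                  gwp[k1 + k * (k2 + k * (k3 + (R_xlen_t)k *
                    ((ci + i) + (R_xlen_t)Cin * (co + j))))] +=
                      acc[4 * i + j];
            }
  }
  NumericVector gx((R_xlen_t)N * Cin);
  gx.attr("dim") = xd;
  unpad3(gxpad.data(), REAL(gx), D1, D2, D3, Cin, p);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
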