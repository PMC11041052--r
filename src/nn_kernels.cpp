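// Dense numeric kernels for the attention-gate U-Net: same-padded 3D
// convolution (im2col + GEMM), factor-2 max-pooling and trilinear
// upsampling, each with its adjoint for backpropagation.
//
// Array convention (R column-major): feature maps are 4D (X, Y, Z, C);
// conv weights are 5D (kx, ky, kz, Cin, Cout). 2D networks use kz = 1 and
// a z pooling factor of 1, so one code path serves both modes.
//
// The im2col buffer spans a chunk of output z-slices at a time so the
// GEMMs are large enough for BLAS to run efficiently while memory stays
// bounded (~tens of MB at the package's working sizes).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int chunk_depth(int X, int Y, int Z) {
  int cz = 4096 / std::max(1, X * Y);
  if (cz < 1) cz = 1;
  if (cz > Z) cz = Z;
  return cz;
}

// Gather the kx*ky*kz*Cin receptive-field columns for output z-slices
// [oz0, oz0+cz). col is (X*Y*cz) x (kx*ky*kz*Cin); out-of-bounds taps
// stay zero.
static void build_col(const double* x, int X, int Y, int Z, int Cin,
                      int kx, int ky, int kz, int oz0, int cz,
                      arma::mat& col) {
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  col.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int k = 0; k < kz; ++k) {
      for (int j = 0; j < ky; ++j) {
        for (int i = 0; i < kx; ++i) {
          const int c = i + kx * (j + ky * (k + kz * ci));
          double* colptr = col.colptr(c);
          const int ox0 = std::max(0, px - i);
          const int ox1 = std::min(X, X + px - i);
          for (int ozc = 0; ozc < cz; ++ozc) {
            const int z = oz0 + ozc + k - pz;
            if (z < 0 || z >= Z) continue;
            const double* xbase = x + (size_t)X * Y * (z + (size_t)Z * ci);
            double* cbase = colptr + (size_t)X * Y * ozc;
            for (int oy = 0; oy < Y; ++oy) {
              const int yy = oy + j - py;
              if (yy < 0 || yy >= Y) continue;
              const double* xrow = xbase + (size_t)X * yy;
              double* crow = cbase + (size_t)X * oy;
              for (int ox = ox0; ox < ox1; ++ox)
                crow[ox] = xrow[ox + i - px];
            }
          }
        }
      }
    }
  }
}

// Adjoint of build_col: scatter-add column gradients back onto the input.
static void scatter_col(const arma::mat& col, double* gx, int X, int Y,
                        int Z, int Cin, int kx, int ky, int kz, int oz0,
                        int cz) {
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int k = 0; k < kz; ++k) {
      for (int j = 0; j < ky; ++j) {
        for (int i = 0; i < kx; ++i) {
          const int c = i + kx * (j + ky * (k + kz * ci));
          const double* colptr = col.colptr(c);
          const int ox0 = std::max(0, px - i);
          const int ox1 = std::min(X, X + px - i);
          for (int ozc = 0; ozc < cz; ++ozc) {
            const int z = oz0 + ozc + k - pz;
            if (z < 0 || z >= Z) continue;
            double* xbase = gx + (size_t)X * Y * (z + (size_t)Z * ci);
            const double* cbase = colptr + (size_t)X * Y * ozc;
            for (int oy = 0; oy < Y; ++oy) {
              const int yy = oy + j - py;
              if (yy < 0 || yy >= Y) continue;
              double* xrow = xbase + (size_t)X * yy;
              const double* crow = cbase + (size_t)X * oy;
              for (int ox = ox0; ox < ox1; ++ox)
                xrow[ox + i - px] += crow[ox];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, IntegerVector wdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  const size_t K = (size_t)kx * ky * kz * Cin;
  arma::mat W(w.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout, false, true);
  NumericVector y((size_t)X * Y * Z * Cout);
  if (kx == 1 && ky == 1 && kz == 1) {
    // pointwise convolution: one big GEMM over all voxels
    arma::mat Xm(x.begin(), (size_t)X * Y * Z, Cin, false, true);
    arma::mat Ym(y.begin(), (size_t)X * Y * Z, Cout, false, true);
    Ym = Xm * W;
    Ym.each_row() += bv;
    y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
    return y;
  }
  const int cz = chunk_depth(X, Y, Z);
  arma::mat col((size_t)X * Y * cz, K);
  for (int oz0 = 0; oz0 < Z; oz0 += cz) {
    const int czi = std::min(cz, Z - oz0);
    build_col(x.begin(), X, Y, Z, Cin, kx, ky, kz, oz0, czi, col);
    arma::mat ys;
    if (czi == cz) ys = col * W;
    else ys = col.rows(0, (size_t)X * Y * czi - 1) * W;
    ys.each_row() += bv;
    for (int co = 0; co < Cout; ++co)
      for (int ozc = 0; ozc < czi; ++ozc)
        std::copy(ys.colptr(co) + (size_t)X * Y * ozc,
                  ys.colptr(co) + (size_t)X * Y * (ozc + 1),
                  y.begin() + (size_t)X * Y * (oz0 + ozc + (size_t)Z * co));
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector xdim, IntegerVector wdim, bool need_gx) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  const size_t K = (size_t)kx * ky * kz * Cin;
  arma::mat W(w.begin(), K, Cout, false, true);
  arma::mat GW(K, Cout, arma::fill::zeros);
  arma::rowvec GB(Cout, arma::fill::zeros);
  NumericVector gx(need_gx ? (size_t)X * Y * Z * Cin : 0);
  if (kx == 1 && ky == 1 && kz == 1) {
    arma::mat Xm(x.begin(), (size_t)X * Y * Z, Cin, false, true);
    arma::mat Gy(gy.begin(), (size_t)X * Y * Z, Cout, false, true);
    GW = Xm.t() * Gy;
    GB = arma::sum(Gy, 0);
    if (need_gx) {
      arma::mat Gx(gx.begin(), (size_t)X * Y * Z, Cin, false, true);
      Gx = Gy * W.t();
      gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
    }
    NumericVector gwv1(GW.begin(), GW.end());
    gwv1.attr("dim") = wdim;
    NumericVector gbv1(GB.begin(), GB.end());
    return List::create(_["gw"] = gwv1, _["gb"] = gbv1, _["gx"] = gx);
  }
  const int cz = chunk_depth(X, Y, Z);
  arma::mat col((size_t)X * Y * cz, K);
  arma::mat gys((size_t)X * Y * cz, Cout);
  for (int oz0 = 0; oz0 < Z; oz0 += cz) {
    const int czi = std::min(cz, Z - oz0);
    const size_t rows = (size_t)X * Y * czi;
    build_col(x.begin(), X, Y, Z, Cin, kx, ky, kz, oz0, czi, col);
    for (int co = 0; co < Cout; ++co)
      for (int ozc = 0; ozc < czi; ++ozc)
        std::copy(gy.begin() + (size_t)X * Y * (oz0 + ozc + (size_t)Z * co),
                  gy.begin() + (size_t)X * Y * (oz0 + ozc + (size_t)Z * co) +
                    (size_t)X * Y,
                  gys.colptr(co) + (size_t)X * Y * ozc);
    if (czi == cz) {
      GW += col.t() * gys;
      GB += arma::sum(gys, 0);
      if (need_gx) {
        arma::mat gcol = gys * W.t();
        scatter_col(gcol, gx.begin(), X, Y, Z, Cin, kx, ky, kz, oz0, czi);
      }
    } else {
      arma::mat colv = col.rows(0, rows - 1);
      arma::mat gyv = gys.rows(0, rows - 1);
      GW += colv.t() * gyv;
      GB += arma::sum(gyv, 0);
      if (need_gx) {
        arma::mat gcol = gyv * W.t();
        scatter_col(gcol, gx.begin(), X, Y, Z, Cin, kx, ky, kz, oz0, czi);
      }
    }
  }
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = wdim;
  NumericVector gbv(GB.begin(), GB.end());
  if (need_gx) gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  return List::create(_["gw"] = gwv, _["gb"] = gbv, _["gx"] = gx);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim, IntegerVector pool) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int fx = pool[0], fy = pool[1], fz = pool[2];
  const int OX = X / fx, OY = Y / fy, OZ = Z / fz;
  NumericVector y((size_t)OX * OY * OZ * C);
  IntegerVector idx((size_t)OX * OY * OZ * C);
  size_t t = 0;
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox, ++t) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                const size_t ii = (size_t)(ox * fx + dx) +
                  (size_t)X * ((oy * fy + dy) +
                  (size_t)Y * ((oz * fz + dz) + (size_t)Z * c));
                const double v = x[ii];
                if (v > best) { best = v; bi = ii; }
              }
          y[t] = best;
          idx[t] = (int)bi;
        }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              IntegerVector indim) {
  NumericVector gx((size_t)indim[0] * indim[1] * indim[2] * indim[3]);
  for (R_xlen_t t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  gx.attr("dim") = indim;
  return gx;
}

// Linear interpolation weights for integer-factor upsampling with
// half-voxel alignment: src = (dst + 0.5)/f - 0.5, clamped to the grid.
static void axis_weights(int outn, int inn, int f, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(outn); i1.resize(outn); w1.resize(outn);
  for (int d = 0; d < outn; ++d) {
    double s = (d + 0.5) / f - 0.5;
    if (s < 0) s = 0;
    if (s > inn - 1) s = inn - 1;
    const int a = (int)std::floor(s);
    i0[d] = a;
    i1[d] = std::min(a + 1, inn - 1);
    w1[d] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, IntegerVector xdim,
                               IntegerVector factor) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = X * factor[0], OY = Y * factor[1], OZ = Z * factor[2];
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  axis_weights(OX, X, factor[0], xi0, xi1, xw);
  axis_weights(OY, Y, factor[1], yi0, yi1, yw);
  axis_weights(OZ, Z, factor[2], zi0, zi1, zw);
  NumericVector y((size_t)OX * OY * OZ * C);
  size_t t = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)X * Y * Z * c;
    for (int oz = 0; oz < OZ; ++oz) {
      const double wz1 = zw[oz], wz0 = 1 - wz1;
      const double* pz0 = xc + (size_t)X * Y * zi0[oz];
      const double* pz1 = xc + (size_t)X * Y * zi1[oz];
      for (int oy = 0; oy < OY; ++oy) {
        const double wy1 = yw[oy], wy0 = 1 - wy1;
        const double* p00 = pz0 + (size_t)X * yi0[oy];
        const double* p01 = pz0 + (size_t)X * yi1[oy];
        const double* p10 = pz1 + (size_t)X * yi0[oy];
        const double* p11 = pz1 + (size_t)X * yi1[oy];
        const double w00 = wz0 * wy0, w01 = wz0 * wy1;
        const double w10 = wz1 * wy0, w11 = wz1 * wy1;
        for (int ox = 0; ox < OX; ++ox, ++t) {
          const double wx1 = xw[ox], wx0 = 1 - wx1;
          const int a = xi0[ox], bq = xi1[ox];
          y[t] = w00 * (wx0 * p00[a] + wx1 * p00[bq]) +
                 w01 * (wx0 * p01[a] + wx1 * p01[bq]) +
                 w10 * (wx0 * p10[a] + wx1 * p10[bq]) +
                 w11 * (wx0 * p11[a] + wx1 * p11[bq]);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector gy, IntegerVector xdim,
                               IntegerVector factor) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int OX = X * factor[0], OY = Y * factor[1], OZ = Z * factor[2];
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  axis_weights(OX, X, factor[0], xi0, xi1, xw);
  axis_weights(OY, Y, factor[1], yi0, yi1, yw);
  axis_weights(OZ, Z, factor[2], zi0, zi1, zw);
  NumericVector gx((size_t)X * Y * Z * C);
  size_t t = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = gx.begin() + (size_t)X * Y * Z * c;
    for (int oz = 0; oz < OZ; ++oz) {
      const double wz1 = zw[oz], wz0 = 1 - wz1;
      double* pz0 = xc + (size_t)X * Y * zi0[oz];
      double* pz1 = xc + (size_t)X * Y * zi1[oz];
      for (int oy = 0; oy < OY; ++oy) {
        const double wy1 = yw[oy], wy0 = 1 - wy1;
        double* p00 = pz0 + (size_t)X * yi0[oy];
        double* p01 = pz0 + (size_t)X * yi1[oy];
        double* p10 = pz1 + (size_t)X * yi0[oy];
        double* p11 = pz1 + (size_t)X * yi1[oy];
        const double w00 = wz0 * wy0, w01 = wz0 * wy1;
        const double w10 = wz1 * wy0, w11 = wz1 * wy1;
        for (int ox = 0; ox < OX; ++ox, ++t) {
          const double g = gy[t];
          const double gx0 = g * (1 - xw[ox]), gx1 = g * xw[ox];
          const int a = xi0[ox], bq = xi1[ox];
          p00[a] += w00 * gx0; p00[bq] += w00 * gx1;
          p01[a] += w01 * gx0; p01[bq] += w01 * gx1;
          p10[a] += w10 * gx0; p10[bq] += w10 * gx1;
          p11[a] += w11 * gx0; p11[bq] += w11 * gx1;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gx;
}
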