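// In-plane (axial) rotation with bilinear interpolation, applied to every
// z-slice (and channel) of a 3D/4D volume. Returns the resampled data and
// an (X, Y) validity map flagging positions whose source fell inside the
// original field of view; the TTA merge uses the map to drop padded voxels.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_rotate_inplane(NumericVector x, IntegerVector dims, double angle_deg,
                        double pad) {
  const int X = dims[0], Y = dims[1];
  size_t planes = 1;
  for (int i = 2; i < dims.size(); ++i) planes *= (size_t)dims[i];
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0;
  NumericVector out((size_t)X * Y * planes, pad);
  NumericVector valid((size_t)X * Y);
  for (int oy = 0; oy < Y; ++oy) {
    for (int ox = 0; ox < X; ++ox) {
      const double dx = ox - cx, dy = oy - cy;
      // output = input rotated by +angle, i.e. sample input at R(-angle)
      const double sx = cx + ct * dx + st * dy;
      const double sy = cy - st * dx + ct * dy;
      if (sx < 0 || sx > X - 1 || sy < 0 || sy > Y - 1) continue;
      const int i0 = (int)std::floor(sx), j0 = (int)std::floor(sy);
      const int i1 = std::min(i0 + 1, X - 1), j1 = std::min(j0 + 1, Y - 1);
      const double fx = sx - i0, fy = sy - j0;
      const size_t o = (size_t)ox + (size_t)X * oy;
      valid[o] = 1.0;
      for (size_t p = 0; p < planes; ++p) {
        const double* xp = x.begin() + (size_t)X * Y * p;
        out[o + (size_t)X * Y * p] =
          (1 - fy) * ((1 - fx) * xp[i0 + (size_t)X * j0] +
                      fx * xp[i1 + (size_t)X * j0]) +
          fy * ((1 - fx) * xp[i0 + (size_t)X * j1] +
                fx * xp[i1 + (size_t)X * j1]);
      }
    }
  }
  out.attr("dim") = dims;
  valid.attr("dim") = IntegerVector::create(X, Y);
  return List::create(_["data"] = out, _["valid"] = valid);
}
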