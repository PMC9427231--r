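#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Apply one composed rigid transform (rotation about the slice center into
// possibly enlarged bounds, then translation) to every depth slice of a
// (H, W, D) volume, in a single interpolation pass per slice.
// Inverse mapping with bilinear (or nearest) sampling; out-of-source pixels
// take fill. Angles in degrees; positive rotates content counterclockwise
// in (row, col) coordinates. dy/dx are the row/column shifts in voxels.
// [[Rcpp::export]]
NumericVector warp_slices(NumericVector x, IntegerVector dims,
                          int out_h, int out_w,
                          double angle_deg, double dy, double dx,
                          double fill, bool nearest) {
  const int H = dims[0], W = dims[1], D = dims[2];
  NumericVector out((R_xlen_t)out_h * out_w * D);
  out.attr("dim") = IntegerVector::create(out_h, out_w, D);
  const double th = angle_deg * M_PI / 180.0;
  const double ca = std::cos(th), sa = std::sin(th);
  // 0-based slice centers
  const double ciy = (H - 1) / 2.0, cix = (W - 1) / 2.0;
  const double coy = (out_h - 1) / 2.0, cox = (out_w - 1) / 2.0;
  const double* px = x.begin();
  double* po = out.begin();
  for (int k = 0; k < D; ++k) {
    const double* sl = px + (R_xlen_t)H * W * k;
    double* ol = po + (R_xlen_t)out_h * out_w * k;
    for (int jo = 0; jo < out_w; ++jo) {
      for (int io = 0; io < out_h; ++io) {
        const double uy = io - dy - coy, ux = jo - dx - cox;
        // inverse rotation R(-theta)
        const double sy = ca * uy + sa * ux + ciy;
        const double sx = -sa * uy + ca * ux + cix;
        double v;
        if (nearest) {
          const int iy = (int)std::lround(sy), ix = (int)std::lround(sx);
          v = (iy < 0 || iy >= H || ix < 0 || ix >= W) ? fill : sl[iy + (R_xlen_t)H * ix];
        } else {
          const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
          const double fy = sy - y0, fx = sx - x0;
          double acc = 0.0;
          for (int b = 0; b < 2; ++b) {
            for (int a = 0; a < 2; ++a) {
              const double w = (a ? fy : 1 - fy) * (b ? fx : 1 - fx);
              if (w == 0.0) continue;
              const int yy = y0 + a, xx = x0 + b;
              const double s = (yy < 0 || yy >= H || xx < 0 || xx >= W)
                                 ? fill : sl[yy + (R_xlen_t)H * xx];
              acc += w * s;
            }
          }
          v = acc;
        }
        ol[io + (R_xlen_t)out_h * jo] = v;
      }
    }
  }
  return out;
}
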