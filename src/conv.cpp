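#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct 3x3x3, stride-1, zero-padded convolution over a batch.
// x: (B*N) x Cin activation matrix, sample-major rows, n = i + H*(j + W*k).
// w: R array [3,3,3,Cin,Cout] (flat index di + 3*dj + 9*dk + 27*(c + Cin*o)).
// Returns (B*N) x Cout, optionally with ReLU fused.
// [[Rcpp::export]]
NumericMatrix conv3_direct(NumericMatrix x, IntegerVector dims, int B,
                           NumericVector w, NumericVector b, bool relu) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const R_xlen_t N = (R_xlen_t)H * W * D;
  const int cin = x.ncol();
  const int cout = b.size();
  NumericMatrix y(x.nrow(), cout);
  const double* pw = w.begin();
  for (int o = 0; o < cout; ++o) {
    double* yo = &y(0, 0) + (R_xlen_t)o * x.nrow();
    const double bo = b[o];
    for (R_xlen_t n = 0; n < x.nrow(); ++n) yo[n] = bo;
    for (int c = 0; c < cin; ++c) {
      const double* xc = &x(0, 0) + (R_xlen_t)c * x.nrow();
      for (int dk = 0; dk < 3; ++dk) {
        for (int dj = 0; dj < 3; ++dj) {
          for (int di = 0; di < 3; ++di) {
            const double wv = pw[di + 3 * dj + 9 * dk + 27 * ((R_xlen_t)c + (R_xlen_t)cin * o)];
            if (wv == 0.0) continue;
            const int i0 = (di == 0) ? 1 : 0;
            const int i1 = (di == 2) ? H - 1 : H;
            const int ioff = di - 1;
            for (int s = 0; s < B; ++s) {
              const R_xlen_t sbase = (R_xlen_t)s * N;
              for (int k = 0; k < D; ++k) {
                const int kk = k + dk - 1;
                if (kk < 0 || kk >= D) continue;
                for (int j = 0; j < W; ++j) {
                  const int jj = j + dj - 1;
                  if (jj < 0 || jj >= W) continue;
                  double* yrow = yo + sbase + (R_xlen_t)H * (j + (R_xlen_t)W * k);
                  const double* xrow = xc + sbase + (R_xlen_t)H * (jj + (R_xlen_t)W * kk) + ioff;
                  for (int i = i0; i < i1; ++i) yrow[i] += wv * xrow[i];
                }
              }
            }
          }
        }
      }
    }
  }
  if (relu) {
    double* py = y.begin();
    const R_xlen_t tot = (R_xlen_t)y.nrow() * cout;
    for (R_xlen_t t = 0; t < tot; ++t) if (py[t] < 0.0) py[t] = 0.0;
  }
  return y;
}

// Gradient w.r.t. the input: dx[n_in, c] = sum_{t, o} w[t, c, o] * dy[n_out, o]
// where n_in = n_out + offset(t), i.e. correlation with the flipped kernel.
// [[Rcpp::export]]
NumericMatrix conv3_grad_x(NumericMatrix dy, IntegerVector dims, int B,
                           NumericVector w, int cin) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const R_xlen_t N = (R_xlen_t)H * W * D;
  const int cout = dy.ncol();
  NumericMatrix dx(dy.nrow(), cin);
  const double* pw = w.begin();
  for (int o = 0; o < cout; ++o) {
    const double* dyo = &dy(0, 0) + (R_xlen_t)o * dy.nrow();
    for (int c = 0; c < cin; ++c) {
      double* dxc = &dx(0, 0) + (R_xlen_t)c * dy.nrow();
      for (int dk = 0; dk < 3; ++dk) {
        for (int dj = 0; dj < 3; ++dj) {
          for (int di = 0; di < 3; ++di) {
            const double wv = pw[di + 3 * dj + 9 * dk + 27 * ((R_xlen_t)c + (R_xlen_t)cin * o)];
            if (wv == 0.0) continue;
            const int i0 = (di == 0) ? 1 : 0;
            const int i1 = (di == 2) ? H - 1 : H;
            const int ioff = di - 1;
            for (int s = 0; s < B; ++s) {
              const R_xlen_t sbase = (R_xlen_t)s * N;
              for (int k = 0; k < D; ++k) {
                const int kk = k + dk - 1;
                if (kk < 0 || kk >= D) continue;
                for (int j = 0; j < W; ++j) {
                  const int jj = j + dj - 1;
                  if (jj < 0 || jj >= W) continue;
                  const double* dyrow = dyo + sbase + (R_xlen_t)H * (j + (R_xlen_t)W * k);
                  double* dxrow = dxc + sbase + (R_xlen_t)H * (jj + (R_xlen_t)W * kk) + ioff;
                  for (int i = i0; i < i1; ++i) dxrow[i] += wv * dyrow[i];
                }
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Gradient w.r.t. the kernel: dw[t, c, o] = sum_n x[n + offset(t), c] * dy[n, o].
// Returns the flat [3,3,3,Cin,Cout] gradient vector.
// [[Rcpp::export]]
NumericVector conv3_grad_w(NumericMatrix x, NumericMatrix dy,
                           IntegerVector dims, int B) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const R_xlen_t N = (R_xlen_t)H * W * D;
  const int cin = x.ncol(), cout = dy.ncol();
  NumericVector dw((R_xlen_t)27 * cin * cout);
  double* pdw = dw.begin();
  for (int o = 0; o < cout; ++o) {
    const double* dyo = &dy(0, 0) + (R_xlen_t)o * dy.nrow();
    for (int c = 0; c < cin; ++c) {
      const double* xc = &x(0, 0) + (R_xlen_t)c * x.nrow();
      for (int dk = 0; dk < 3; ++dk) {
        for (int dj = 0; dj < 3; ++dj) {
          for (int di = 0; di < 3; ++di) {
            const int i0 = (di == 0) ? 1 : 0;
            const int i1 = (di == 2) ? H - 1 : H;
            const int ioff = di - 1;
            double acc = 0.0;
            for (int s = 0; s < B; ++s) {
              const R_xlen_t sbase = (R_xlen_t)s * N;
              for (int k = 0; k < D; ++k) {
                const int kk = k + dk - 1;
                if (kk < 0 || kk >= D) continue;
                for (int j = 0; j < W; ++j) {
                  const int jj = j + dj - 1;
                  if (jj < 0 || jj >= W) continue;
                  const double* dyrow = dyo + sbase + (R_xlen_t)H * (j + (R_xlen_t)W * k);
                  const double* xrow = xc + sbase + (R_xlen_t)H * (jj + (R_xlen_t)W * kk) + ioff;
                  for (int i = i0; i < i1; ++i) acc += xrow[i] * dyrow[i];
                }
              }
            }
            pdw[di + 3 * dj + 9 * dk + 27 * ((R_xlen_t)c + (R_xlen_t)cin * o)] = acc;
          }
        }
      }
    }
  }
  return dw;
}

// Fused Adam update: one pass over the tensor, returning updated
// parameter and moment vectors.
// [[Rcpp::export]]
List adam_fused(NumericVector p, NumericVector g, NumericVector m,
                NumericVector v, double lr, double beta1, double beta2,
                double eps, double t) {
  const R_xlen_t n = p.size();
  NumericVector p2(clone(p)), m2(clone(m)), v2(clone(v));
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  double* pp = p2.begin(); double* pm = m2.begin(); double* pv = v2.begin();
  const double* pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
  p2.attr("dim") = p.attr("dim");
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
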