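// Sub-pixel image sampling and displacement-field warping.
//
// Coordinates are 0-based, pixel-centred: x indexes columns (longitudinal
// axis), y indexes rows (depth axis).  Out-of-domain samples are edge
// replicated.  Bicubic uses the Catmull-Rom / cubic-convolution kernel
// (a = -0.5).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double cubw(double t) {
  // cubic convolution weight, a = -0.5
  double a = -0.5, at = std::fabs(t);
  if (at <= 1.0) return (a + 2.0) * at * at * at - (a + 3.0) * at * at + 1.0;
  if (at < 2.0)  return a * at * at * at - 5.0 * a * at * at + 8.0 * a * at - 4.0 * a;
  return 0.0;
}

static double sample_one_bicubic(const double* img, int H, int W,
                                 double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double wx[4], wy[4];
  for (int k = 0; k < 4; ++k) {
    wx[k] = cubw(fx - (k - 1));
    wy[k] = cubw(fy - (k - 1));
  }
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    int xc = clampi(x0 + j - 1, 0, W - 1);
    const double* col = img + (size_t)xc * H;
    double rowacc = 0.0;
    for (int i = 0; i < 4; ++i)
      rowacc += wy[i] * col[clampi(y0 + i - 1, 0, H - 1)];
    acc += wx[j] * rowacc;
  }
  return acc;
}

static double sample_one_bilinear(const double* img, int H, int W,
                                  double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  int x0c = clampi(x0, 0, W - 1), x1c = clampi(x0 + 1, 0, W - 1);
  int y0c = clampi(y0, 0, H - 1), y1c = clampi(y0 + 1, 0, H - 1);
  double v00 = img[(size_t)x0c * H + y0c], v01 = img[(size_t)x1c * H + y0c];
  double v10 = img[(size_t)x0c * H + y1c], v11 = img[(size_t)x1c * H + y1c];
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// [[Rcpp::export(name = ".sample_image")]]
NumericVector sample_image(NumericMatrix img, NumericVector x, NumericVector y,
                           std::string method) {
  int H = img.nrow(), W = img.ncol();
  if (x.size() != y.size()) stop("x and y must have equal length");
  bool cubic = (method == "bicubic");
  NumericVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k)
    out[k] = cubic ? sample_one_bicubic(img.begin(), H, W, x[k], y[k])
                   : sample_one_bilinear(img.begin(), H, W, x[k], y[k]);
  return out;
}

// Backward warp: out(r, c) = img(c - u(r, c), r - v(r, c)) in (x, y) terms.
// [[Rcpp::export(name = ".warp_backward_cpp")]]
NumericMatrix warp_backward_cpp(NumericMatrix img, NumericMatrix u,
                                NumericMatrix v, std::string method) {
  int H = img.nrow(), W = img.ncol();
  bool cubic = (method == "bicubic");
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double xs = c - u(r, c), ys = r - v(r, c);
      out(r, c) = cubic ? sample_one_bicubic(img.begin(), H, W, xs, ys)
                        : sample_one_bilinear(img.begin(), H, W, xs, ys);
    }
  return out;
}

// Forward (Lagrangian) warp: u, v are displacements of material points, so
// the deformed image satisfies  I_def(X + U(X)) = I_ref(X).  The material
// coordinate X(x) is recovered per output pixel by damped fixed-point
// iteration of X = x - U(X), with U sampled bilinearly between pixels.
// [[Rcpp::export(name = ".warp_forward_cpp")]]
NumericMatrix warp_forward_cpp(NumericMatrix img, NumericMatrix u,
                               NumericMatrix v, std::string method,
                               int max_iter, double tol) {
  int H = img.nrow(), W = img.ncol();
  bool cubic = (method == "bicubic");
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double X = c, Y = r;
      for (int it = 0; it < max_iter; ++it) {
        double uu = sample_one_bilinear(u.begin(), H, W, X, Y);
        double vv = sample_one_bilinear(v.begin(), H, W, X, Y);
        double Xn = c - uu, Yn = r - vv;
        double d = std::fabs(Xn - X) + std::fabs(Yn - Y);
        // damping keeps the iteration stable when |grad U| approaches 1
        X += 0.8 * (Xn - X);
        Y += 0.8 * (Yn - Y);
        if (d < tol) break;
      }
      out(r, c) = cubic ? sample_one_bicubic(img.begin(), H, W, X, Y)
                        : sample_one_bilinear(img.begin(), H, W, X, Y);
    }
  return out;
}
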