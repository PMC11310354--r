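// Low-level neural-network primitives: 3x3 same-padding convolution and
// 2x2 max pooling, forward and backward, over batched activation arrays.
//
// Activation layout everywhere: column-major R array with dim (H, W, C, B).
// Convolution weights: matrix (9*Cin) x Cout; row index = c*9 + kx*3 + ky
// with kx, ky in {0,1,2} offsets (dx, dy) = (kx-1, ky-1).  The layout only
// has to be consistent between the forward and backward kernels and the R
// initialiser.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector num4(int H, int W, int C, int B) {
  NumericVector o((R_xlen_t)H * W * C * B);
  o.attr("dim") = IntegerVector::create(H, W, C, B);
  return o;
}

static IntegerVector int4(int H, int W, int C, int B) {
  IntegerVector o((R_xlen_t)H * W * C * B);
  o.attr("dim") = IntegerVector::create(H, W, C, B);
  return o;
}

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, B) array");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

// im2col for a single sample (H x W x C cube view) -> (H*W) x (9*C) matrix.
static void im2col3(const double* x, int H, int W, int C, arma::mat& out) {
  out.zeros(H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < 3; ++kx) {
      int dx = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        int dy = ky - 1;
        int col = c * 9 + kx * 3 + ky;
        double* o = out.colptr(col);
        int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc + (size_t)(j + dx) * H + dy;
          double* dst = o + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
}

// scatter-add transpose of im2col3: cols (H*W) x (9*C) -> H x W x C
static void col2im3(const arma::mat& cols, int H, int W, int C, double* x) {
  std::fill(x, x + (size_t)H * W * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kx = 0; kx < 3; ++kx) {
      int dx = kx - 1;
      for (int ky = 0; ky < 3; ++ky) {
        int dy = ky - 1;
        int col = c * 9 + kx * 3 + ky;
        const double* o = cols.colptr(col);
        int j0 = std::max(0, -dx), j1 = std::min(W, W - dx);
        int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
        for (int j = j0; j < j1; ++j) {
          double* dst = xc + (size_t)(j + dx) * H + dy;
          const double* src = o + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix w, NumericVector b) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (w.nrow() != 9 * C) stop("weight rows must equal 9 * input channels");
  int F = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), F, false);
  arma::rowvec bv(b.begin(), F);

  NumericVector out = num4(H, W, F, B);
  arma::mat cols;
  for (int bi = 0; bi < B; ++bi) {
    im2col3(x.begin() + (size_t)bi * H * W * C, H, W, C, cols);
    arma::mat y = cols * wm;              // (H*W) x F
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (size_t)bi * H * W * F);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dy) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  int F = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), F, false);

  NumericVector dx = num4(H, W, C, B);
  arma::mat dw(9 * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);

  arma::mat cols;
  for (int bi = 0; bi < B; ++bi) {
    im2col3(x.begin() + (size_t)bi * H * W * C, H, W, C, cols);
    arma::mat dyb(dy.begin() + (size_t)bi * H * W * F, H * W, F, false);
    dw += cols.t() * dyb;
    db += arma::sum(dyb, 0);
    arma::mat dcols = dyb * wm.t();       // (H*W) x (9*C)
    col2im3(dcols, H, W, C, dx.begin() + (size_t)bi * H * W * C);
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(9 * C, F, dw.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2.  Returns pooled array and 1-based argmax linear
// indices into the input array (for the backward pass).
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, B);
  IntegerVector idx = int4(Ho, Wo, C, B);
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      size_t in0 = ((size_t)bi * C + c) * H * W;
      size_t out0 = ((size_t)bi * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = in0 + (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          int am = 0;
          double mv = x[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (x[cand[k]] > mv) { mv = x[cand[k]]; am = k; }
          y[out0 + (size_t)j * Ho + i] = mv;
          idx[out0 + (size_t)j * Ho + i] = (int)cand[am] + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector in_dim) {
  NumericVector dx = num4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k] - 1] += dy[k];
  return dx;
}
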