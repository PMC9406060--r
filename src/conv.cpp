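// Minimal single-threaded 2-D convolution primitives (im2col + GEMM).
// Layouts (all row-vectors per sample, 0-based in C++):
//   sample feature vector: index(c, h, w) = (c*H + h)*W + w
//   weight matrix row oc:  index(c, kh, kw) = (c*K + kh)*K + kw
//   output feature vector: index(oc, oh, ow) = (oc*OH + oh)*OW + ow
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int K, int S, int P) {
  return (H + 2 * P - K) / S + 1;
}

static void im2col_one(const arma::vec &x, int C, int H, int W,
                       int K, int S, int P, arma::mat &col) {
  const int OH = out_dim(H, K, S, P), OW = out_dim(W, K, S, P);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.memptr() + (size_t)c * H * W;
    for (int kh = 0; kh < K; ++kh) {
      for (int kw = 0; kw < K; ++kw) {
        const int r = (c * K + kh) * K + kw;
        for (int oh = 0; oh < OH; ++oh) {
          const int ih = oh * S - P + kh;
          const bool hin = (ih >= 0 && ih < H);
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * S - P + kw;
            col(r, oh * OW + ow) =
                (hin && iw >= 0 && iw < W) ? xc[(size_t)ih * W + iw] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat &col, int C, int H, int W,
                       int K, int S, int P, arma::vec &x) {
  const int OH = out_dim(H, K, S, P), OW = out_dim(W, K, S, P);
  x.zeros();
  for (int c = 0; c < C; ++c) {
    double *xc = x.memptr() + (size_t)c * H * W;
    for (int kh = 0; kh < K; ++kh) {
      for (int kw = 0; kw < K; ++kw) {
        const int r = (c * K + kh) * K + kw;
        for (int oh = 0; oh < OH; ++oh) {
          const int ih = oh * S - P + kh;
          if (ih < 0 || ih >= H) continue;
          for (int ow = 0; ow < OW; ++ow) {
            const int iw = ow * S - P + kw;
            if (iw < 0 || iw >= W) continue;
            xc[(size_t)ih * W + iw] += col(r, oh * OW + ow);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix conv2d_forward_cpp(const NumericMatrix &X,
                                 const NumericMatrix &Wt,
                                 const NumericVector &b,
                                 int C, int H, int W, int K, int S, int P) {
  const int N = X.nrow();
  const int OC = Wt.nrow();
  const int OH = out_dim(H, K, S, P), OW = out_dim(W, K, S, P);
  if (X.ncol() != C * H * W) stop("input width %d != C*H*W = %d", X.ncol(), C * H * W);
  if (Wt.ncol() != C * K * K) stop("weight width %d != C*K*K = %d", Wt.ncol(), C * K * K);
  if (b.size() != OC) stop("bias length %d != output channels %d", b.size(), OC);

  arma::mat Wm(Wt.begin(), OC, C * K * K);  // copies (column-major)
  arma::vec bv(b.begin(), OC);
  arma::mat col(C * K * K, OH * OW);
  arma::vec x(C * H * W);
  NumericMatrix out(N, OC * OH * OW);

  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < C * H * W; ++j) x[j] = X(n, j);
    im2col_one(x, C, H, W, K, S, P, col);
    arma::mat Y = Wm * col;   // OC x OH*OW
    Y.each_col() += bv;
    for (int oc = 0; oc < OC; ++oc)
      for (int j = 0; j < OH * OW; ++j)
        out(n, oc * OH * OW + j) = Y(oc, j);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(const NumericMatrix &X,
                         const NumericMatrix &Wt,
                         const NumericMatrix &dY,
                         int C, int H, int W, int K, int S, int P,
                         bool need_dx) {
  const int N = X.nrow();
  const int OC = Wt.nrow();
  const int OH = out_dim(H, K, S, P), OW = out_dim(W, K, S, P);
  if (dY.nrow() != N) stop("dY rows %d != N = %d", dY.nrow(), N);
  if (dY.ncol() != OC * OH * OW)
    stop("dY width %d != OC*OH*OW = %d", dY.ncol(), OC * OH * OW);

  arma::mat Wm(Wt.begin(), OC, C * K * K);
  arma::mat dW(OC, C * K * K, arma::fill::zeros);
  arma::vec db(OC, arma::fill::zeros);
  arma::mat col(C * K * K, OH * OW);
  arma::mat dYn(OC, OH * OW);
  arma::vec x(C * H * W), dx(C * H * W);
  NumericMatrix dX(need_dx ? N : 1, need_dx ? C * H * W : 1);

  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < C * H * W; ++j) x[j] = X(n, j);
    im2col_one(x, C, H, W, K, S, P, col);
    for (int oc = 0; oc < OC; ++oc)
      for (int j = 0; j < OH * OW; ++j)
        dYn(oc, j) = dY(n, oc * OH * OW + j);
    dW += dYn * col.t();
    db += arma::sum(dYn, 1);
    if (need_dx) {
      arma::mat dcol = Wm.t() * dYn;
      col2im_one(dcol, C, H, W, K, S, P, dx);
      for (int j = 0; j < C * H * W; ++j) dX(n, j) = dx[j];
    }
  }
  return List::create(Named("dW") = wrap(arma::mat(dW)),
                      Named("db") = wrap(arma::vec(db)),
                      Named("dX") = dX);
}
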