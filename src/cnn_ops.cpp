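// Compiled kernels for the network engine: 3x3 same-size convolution and
// 2x2 max pooling, forward and backward. Activation arrays are column-major
// (H, W, C, N). Weight matrices are (Cout x 9*Cin) with column order
// (dr fastest, dc, cin), matching the column-major layout of a
// (3, 3, Cin, Cout) kernel array. im2col is assembled for the whole batch
// so each pass is a single BLAS GEMM per layer. The pure-R reference
// implementations in R/layers.R compute the same quantities and serve as
// test oracles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill columns [n*H*W, (n+1)*H*W) of `cols` with the im2col expansion
// (3x3, stride 1, pad 1) of one sample laid out at `x` with C channels.
static void im2col3_into(const double* x, int H, int W, int C,
                         arma::mat& cols, size_t col0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dc = 0; dc < 3; ++dc)
      for (int dr = 0; dr < 3; ++dr) {
        const int row = dr + 3 * dc + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dc - 1;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, 1 - dr);
          const int i1 = std::min(H, H + 1 - dr);
          double* dst = cols.colptr(col0 + (size_t)H * j) + row;
          const double* src = xc + (size_t)H * sj + dr - 1;
          const size_t step = cols.n_rows;
          for (int i = i0; i < i1; ++i)
            dst[(size_t)i * step] = src[i];
        }
      }
  }
}

static arma::mat im2col3_batch(const double* x, int H, int W, int C, int N) {
  arma::mat cols(9 * C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    im2col3_into(x + (size_t)H * W * C * n, H, W, C, cols, (size_t)H * W * n);
  return cols;
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd_cpp(NumericVector x, const arma::mat& w,
                              const arma::vec& b) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.n_rows;
  const size_t hw = (size_t)H * W, per_out = hw * Cout;
  arma::mat y = w * im2col3_batch(&x[0], H, W, C, N);   // Cout x (HW*N)
  y.each_col() += b;
  NumericVector out(per_out * N);
  for (int n = 0; n < N; ++n) {
    double* po = &out[0] + per_out * n;
    for (size_t k = 0; k < hw; ++k) {
      const double* py = y.colptr(hw * n + k);
      for (int co = 0; co < Cout; ++co) po[k + hw * co] = py[co];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector x, NumericVector dy, const arma::mat& w,
                     bool want_dx = true) {
  IntegerVector d = x.attr("dim"), dd = dy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = dd[2];
  const size_t hw = (size_t)H * W, per_in = hw * C, per_out = hw * Cout;
  // dmat: Cout x (HW*N) reordering of dy
  arma::mat dmat(Cout, hw * N);
  for (int n = 0; n < N; ++n) {
    const double* pd = &dy[0] + per_out * n;
    for (size_t k = 0; k < hw; ++k) {
      double* pc = dmat.colptr(hw * n + k);
      for (int co = 0; co < Cout; ++co) pc[co] = pd[k + hw * co];
    }
  }
  arma::mat cols = im2col3_batch(&x[0], H, W, C, N);
  arma::mat dw = dmat * cols.t();                       // Cout x 9C
  arma::vec db = arma::sum(dmat, 1);
  if (!want_dx) {
    return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = R_NilValue);
  }
  // dx: same-size conv of dy with the flipped, channel-transposed kernel
  arma::mat wf(C, 9 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci)
      for (int dc = 0; dc < 3; ++dc)
        for (int dr = 0; dr < 3; ++dr)
          wf(ci, dr + 3 * dc + 9 * co) =
            w(co, (2 - dr) + 3 * (2 - dc) + 9 * ci);
  arma::mat dxm = wf * im2col3_batch(&dy[0], H, W, Cout, N);  // C x (HW*N)
  NumericVector dx(per_in * N);
  for (int n = 0; n < N; ++n) {
    double* px = &dx[0] + per_in * n;
    for (size_t k = 0; k < hw; ++k) {
      const double* pc = dxm.colptr(hw * n + k);
      for (int c = 0; c < C; ++c) px[k + hw * c] = pc[c];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2; trailing odd row/column dropped. `sel` stores
// the within-window argmax (0..3, first-wins on ties) for the backward pass.
// [[Rcpp::export]]
List pool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t per_in = (size_t)H * W, per_out = (size_t)Ho * Wo;
  NumericVector y(per_out * C * N);
  IntegerVector sel(per_out * C * N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* px = &x[0] + s * per_in;
    double* py = &y[0] + s * per_out;
    int* ps = &sel[0] + s * per_out;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int bi = 2 * i, bj = 2 * j;
        const double v[4] = {px[bi + H * bj], px[bi + 1 + H * bj],
                             px[bi + H * (bj + 1)], px[bi + 1 + H * (bj + 1)]};
        int a = 0;
        for (int k = 1; k < 4; ++k) if (v[k] > v[a]) a = k;
        py[i + Ho * j] = v[a];
        ps[i + Ho * j] = a;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["sel"] = sel,
                      _["in_dim"] = IntegerVector::create(H, W, C, N));
}

// [[Rcpp::export]]
NumericVector pool2_bwd_cpp(NumericVector dy, IntegerVector sel,
                            IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t per_in = (size_t)H * W, per_out = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * W * C * N);
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* pd = &dy[0] + s * per_out;
    const int* ps = &sel[0] + s * per_out;
    double* px = &dx[0] + s * per_in;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int a = ps[i + Ho * j];
        const int bi = 2 * i + (a == 1 || a == 3);
        const int bj = 2 * j + (a >= 2);
        px[bi + H * bj] += pd[i + Ho * j];
      }
  }
  dx.attr("dim") = in_dim;
  return dx;
}
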