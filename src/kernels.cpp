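// Compiled kernels for the hot path: 2-D (grouped) convolution and max
// pooling, forward and backward.  Everything else in the network is cheap
// enough to stay in vectorised R.
//
// Feature maps are numeric arrays with dim c(C, H, W) (channel fastest,
// matching R's column-major order), mapped here onto arma::cube(C, H, W).
// Convolution weights are arrays with dim c(k, k, c_in/groups, c_out):
// dim 1 indexes the kernel row (along H), dim 2 the kernel column (along W).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false);
}

static NumericVector cube_to_r(const arma::cube& y) {
  NumericVector out(y.n_elem);
  std::copy(y.memptr(), y.memptr() + y.n_elem, out.begin());
  out.attr("dim") = IntegerVector::create(y.n_rows, y.n_cols, y.n_slices);
  return out;
}

// im2col for one group: rows = cg*k*k (index dy + k*dx + k*k*c),
// cols = Hout*Wout (index oh + Hout*ow).
static void im2col(const arma::cube& x, int c0, int cg, int k, int s, int pad,
                   int Hout, int Wout, arma::mat& M) {
  const int H = x.n_cols, W = x.n_slices;
  M.zeros();
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const int col = oh + Hout * ow;
      for (int c = 0; c < cg; ++c) {
        for (int dx = 0; dx < k; ++dx) {
          const int iw = ow * s - pad + dx;
          if (iw < 0 || iw >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int ih = oh * s - pad + dy;
            if (ih < 0 || ih >= H) continue;
            M(dy + k * dx + k * k * c, col) = x(c0 + c, ih, iw);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& M, int c0, int cg, int k, int s, int pad,
                   int Hout, int Wout, arma::cube& dx) {
  const int H = dx.n_cols, W = dx.n_slices;
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const int col = oh + Hout * ow;
      for (int c = 0; c < cg; ++c) {
        for (int dxk = 0; dxk < k; ++dxk) {
          const int iw = ow * s - pad + dxk;
          if (iw < 0 || iw >= W) continue;
          for (int dy = 0; dy < k; ++dy) {
            const int ih = oh * s - pad + dy;
            if (ih < 0 || ih >= H) continue;
            dx(c0 + c, ih, iw) += M(dy + k * dxk + k * k * c, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x_, NumericVector w_,
                            Nullable<NumericVector> b_, int stride, int pad,
                            int groups) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cg = wd[2], cout = wd[3];
  const int Cin = x.n_rows, H = x.n_cols, W = x.n_slices;
  if (Cin != cg * groups) stop("conv2d: input channels do not match weights");
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  if (Hout < 1 || Wout < 1) stop("conv2d: output would be empty");
  const int og = cout / groups;
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * cg, cout, false);
  arma::cube y(cout, Hout, Wout);
  arma::mat M(k * k * cg, Hout * Wout);
  for (int g = 0; g < groups; ++g) {
    im2col(x, g * cg, cg, k, stride, pad, Hout, Wout, M);
    arma::mat Yg = Wm.cols(g * og, (g + 1) * og - 1).t() * M; // og x HW
    for (int col = 0; col < Hout * Wout; ++col)
      for (int o = 0; o < og; ++o)
        y(g * og + o, col % Hout, col / Hout) = Yg(o, col);
  }
  if (b_.isNotNull()) {
    NumericVector b(b_);
    for (int c = 0; c < cout; ++c) y.row(c) += b[c];
  }
  return cube_to_r(y);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x_, NumericVector w_, NumericVector dy_,
                   int stride, int pad, int groups, bool has_bias) {
  arma::cube x = as_cube(x_), dy = as_cube(dy_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cg = wd[2], cout = wd[3];
  const int Hout = dy.n_cols, Wout = dy.n_slices;
  const int og = cout / groups;
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * cg, cout, false);
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  arma::mat dW(k * k * cg, cout, arma::fill::zeros);
  arma::mat M(k * k * cg, Hout * Wout);
  arma::mat dYg(og, Hout * Wout);
  for (int g = 0; g < groups; ++g) {
    for (int col = 0; col < Hout * Wout; ++col)
      for (int o = 0; o < og; ++o)
        dYg(o, col) = dy(g * og + o, col % Hout, col / Hout);
    im2col(x, g * cg, cg, k, stride, pad, Hout, Wout, M);
    dW.cols(g * og, (g + 1) * og - 1) = M * dYg.t();
    arma::mat dM = Wm.cols(g * og, (g + 1) * og - 1) * dYg;
    col2im(dM, g * cg, cg, k, stride, pad, Hout, Wout, dx);
  }
  NumericVector dWr(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  dWr.attr("dim") = IntegerVector::create(k, k, cg, cout);
  List out = List::create(_["dx"] = cube_to_r(dx), _["dw"] = dWr);
  if (has_bias) {
    NumericVector db(cout);
    for (int c = 0; c < cout; ++c)
      db[c] = arma::accu(dy.row(c));
    out["db"] = db;
  }
  return out;
}

// Max pooling with stride/pad; returns the flat argmax per output cell so the
// backward pass can scatter gradients.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x_, int k, int stride, int pad) {
  arma::cube x = as_cube(x_);
  const int C = x.n_rows, H = x.n_cols, W = x.n_slices;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  arma::cube y(C, Hout, Wout);
  IntegerVector idx(C * Hout * Wout);
  for (int ow = 0; ow < Wout; ++ow)
    for (int oh = 0; oh < Hout; ++oh)
      for (int c = 0; c < C; ++c) {
        double best = -1e300; int bi = -1;
        for (int dx = 0; dx < k; ++dx) {
          const int iw = ow * stride - pad + dx;
          if (iw < 0 || iw >= W) continue;
          for (int dyk = 0; dyk < k; ++dyk) {
            const int ih = oh * stride - pad + dyk;
            if (ih < 0 || ih >= H) continue;
            const double v = x(c, ih, iw);
            if (v > best) { best = v; bi = c + C * (ih + H * iw); }
          }
        }
        y(c, oh, ow) = best;
        idx[c + C * (oh + Hout * ow)] = bi;
      }
  List out = List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy_, IntegerVector idx, int C,
                             int H, int W) {
  NumericVector dx(C * H * W);
  for (int i = 0; i < dy_.size(); ++i) dx[idx[i]] += dy_[i];
  dx.attr("dim") = IntegerVector::create(C, H, W);
  return dx;
}
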