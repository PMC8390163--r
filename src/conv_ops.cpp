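// Minimal 2-D convolution and max-pooling kernels for the VGG-style
// backbone: 3x3 convolution with stride 1 and zero padding 1, and 2x2
// max pooling with stride 2. Shapes follow R's column-major layout:
// feature stacks are arma::cube (rows x cols x channels), weights are
// 3 x 3 x c_in x c_out passed as a flat vector with a dim attribute.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void offset_region(int off, int n, int &lo, int &hi) {
  // valid output index range [lo, hi] so that index + off stays in [0, n)
  lo = std::max(0, -off);
  hi = std::min(n - 1, n - 1 - off);
}

// [[Rcpp::export]]
arma::cube cpp_conv3_forward(const arma::cube &x, const NumericVector &w,
                             const arma::vec &b) {
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int h = x.n_rows, wdt = x.n_cols;
  arma::cube y(h, wdt, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < cout; ++co) {
    arma::mat &ys = y.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat &xs = x.slice(ci);
      for (int dj = -1; dj <= 1; ++dj) {
        int c0, c1;
        offset_region(dj, wdt, c0, c1);
        if (c0 > c1) continue;
        for (int di = -1; di <= 1; ++di) {
          int r0, r1;
          offset_region(di, h, r0, r1);
          if (r0 > r1) continue;
          double wv = w[(di + 1) + 3 * (dj + 1) + 9 * ci + 9 * cin * co];
          ys.submat(r0, c0, r1, c1) +=
            wv * xs.submat(r0 + di, c0 + dj, r1 + di, c1 + dj);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_backward(const arma::cube &x, const NumericVector &w,
                        const arma::cube &dy) {
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int h = x.n_rows, wdt = x.n_cols;
  arma::cube dx(h, wdt, cin, arma::fill::zeros);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::vec db(cout);
  for (int co = 0; co < cout; ++co) {
    const arma::mat &dys = dy.slice(co);
    db(co) = arma::accu(dys);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat &xs = x.slice(ci);
      arma::mat &dxs = dx.slice(ci);
      for (int dj = -1; dj <= 1; ++dj) {
        int c0, c1;
        offset_region(dj, wdt, c0, c1);
        if (c0 > c1) continue;
        for (int di = -1; di <= 1; ++di) {
          int r0, r1;
          offset_region(di, h, r0, r1);
          if (r0 > r1) continue;
          const int wi = (di + 1) + 3 * (dj + 1) + 9 * ci + 9 * cin * co;
          double wv = w[wi];
          dxs.submat(r0 + di, c0 + dj, r1 + di, c1 + dj) +=
            wv * dys.submat(r0, c0, r1, c1);
          dw[wi] += arma::accu(
            xs.submat(r0 + di, c0 + dj, r1 + di, c1 + dj) %
            dys.submat(r0, c0, r1, c1));
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(const arma::cube &x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int ho = h / 2, wo = w / 2;
  arma::cube y(ho, wo, c);
  arma::ucube idx(ho, wo, c); // 0-based linear index into the h x w slice
  for (int ch = 0; ch < c; ++ch) {
    const arma::mat &xs = x.slice(ch);
    for (int j = 0; j < wo; ++j) {
      for (int i = 0; i < ho; ++i) {
        int bi = 2 * i, bj = 2 * j, mi = bi, mj = bj;
        double best = xs(bi, bj);
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            if (xs(bi + di, bj + dj) > best) {
              best = xs(bi + di, bj + dj);
              mi = bi + di;
              mj = bj + dj;
            }
        y(i, j, ch) = best;
        idx(i, j, ch) = (arma::uword)(mi + mj * h);
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube &dy, const arma::ucube &idx,
                                 int h, int w) {
  const int c = dy.n_slices;
  arma::cube dx(h, w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    double *dxs = dx.slice(ch).memptr();
    const arma::mat &dys = dy.slice(ch);
    const arma::umat &is = idx.slice(ch);
    for (arma::uword j = 0; j < dys.n_cols; ++j)
      for (arma::uword i = 0; i < dys.n_rows; ++i)
        dxs[is(i, j)] += dys(i, j);
  }
  return dx;
}
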