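// Low-level compute kernels for the multi-kernel CNN layers.
//
// Feature maps are arma::cube with dimensions (H, W, C), matching R's
// column-major array layout dim = c(H, W, C).  Convolutions are "same"
// 3x3 with zero padding; the three parallel kernels (3x3, 3x1, 1x3) are
// folded by the R layer into one effective 3x3 kernel before the call
// (their sum is algebraically a single 3x3 convolution), flattened to a
// (9*C x F) matrix in (ky, kx, c) column-major order.
//
// im2col uses an (H*W x 9C) patch-matrix layout so that each tap is a
// contiguous shifted copy of an image slice (cache-friendly), and the
// convolution itself is one BLAS gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cols(p, r): pixel value at (y + ky - 1, x + kx - 1) of channel c for
// output position p = y + H*x and tap r = c*9 + kx*3 + ky
static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword kx = 0; kx < 3; ++kx) {
      for (arma::uword ky = 0; ky < 3; ++ky) {
        const int dy = (int)ky - 1, dx = (int)kx - 1;
        double* dst = cols.colptr(c * 9 + kx * 3 + ky);
        const int y0 = std::max(0, -dy), y1 = std::min((int)H, (int)H - dy);
        for (arma::uword xx = 0; xx < W; ++xx) {
          const int sx = (int)xx + dx;
          if (sx < 0 || sx >= (int)W) continue;
          const double* src = &x(0, sx, c);
          std::memcpy(dst + xx * H + y0, src + y0 + dy,
                      sizeof(double) * (y1 - y0));
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_mk_conv_forward(const arma::cube& x, const arma::mat& kflat,
                               const arma::vec& bias) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::uword F = kflat.n_cols;
  if (kflat.n_rows != 9 * x.n_slices)
    stop("kernel/input channel mismatch");
  arma::mat cols = im2col3(x);
  arma::mat y = cols * kflat;              // (H*W) x F
  y.each_row() += bias.t();
  arma::cube out(H, W, F);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * H * W * F);
  return out;
}

// [[Rcpp::export]]
List cpp_mk_conv_backward(const arma::cube& x, const arma::mat& kflat,
                          const arma::cube& dy) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword F = dy.n_slices;
  arma::mat cols = im2col3(x);             // HW x 9C
  const arma::mat dymat(const_cast<double*>(dy.memptr()), H * W, F,
                        false, true);
  arma::mat dk = cols.t() * dymat;         // 9C x F
  arma::vec db = arma::sum(dymat, 0).t();
  arma::mat dcols = dymat * kflat.t();     // HW x 9C
  // col2im: scatter-add each tap column back onto the input grid
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword kx = 0; kx < 3; ++kx) {
      for (arma::uword ky = 0; ky < 3; ++ky) {
        const int dyo = (int)ky - 1, dxo = (int)kx - 1;
        const double* src = dcols.colptr(c * 9 + kx * 3 + ky);
        const int y0 = std::max(0, -dyo), y1 = std::min((int)H, (int)H - dyo);
        for (arma::uword xx = 0; xx < W; ++xx) {
          const int sx = (int)xx + dxo;
          if (sx < 0 || sx >= (int)W) continue;
          double* dst = &dx(0, sx, c);
          const double* s = src + xx * H + y0;
          double* d = dst + y0 + dyo;
          for (int yy = y0; yy < y1; ++yy) *d++ += *s++;
        }
      }
    }
  }
  return List::create(_["dk"] = dk, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::cube& x, int n, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (n > H || n > W) stop("pooling window larger than input");
  const int Ho = (H - n) / stride + 1, Wo = (W - n) / stride + 1;
  arma::cube y(Ho, Wo, C);
  IntegerMatrix amax(Ho * Wo, C);          // 0-based linear index into H*W
  for (int c = 0; c < C; ++c) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int kx = 0; kx < n; ++kx) {
          for (int ky = 0; ky < n; ++ky) {
            const int yy = yo * stride + ky, xx = xo * stride + kx;
            const double v = x(yy, xx, c);
            if (v > best) { best = v; bi = yy + H * xx; }
          }
        }
        y(yo, xo, c) = best;
        amax(yo + Ho * xo, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const IntegerMatrix& argmax,
                                const arma::cube& dy, int H, int W) {
  const int C = dy.n_slices, HoWo = dy.n_rows * dy.n_cols;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = dy.slice(c).memptr();
    double* out = dx.slice(c).memptr();
    for (int i = 0; i < HoWo; ++i) out[argmax(i, c)] += g[i];
  }
  return dx;
}

// Connected-component labeling of a binary mask (8-connectivity by
// default), BFS flood fill.  Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy) {
      if (dx == 0 && dy == 0) continue;
      if (connectivity == 4 && dx != 0 && dy != 0) continue;
      nb.push_back({dy, dx});
    }
  int next = 0;
  std::vector<int> stackv;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (mask(y0, x0) == 0 || lab(y0, x0) != 0) continue;
      ++next;
      stackv.push_back(y0 + H * x0);
      lab(y0, x0) = next;
      while (!stackv.empty()) {
        const int p = stackv.back(); stackv.pop_back();
        const int py = p % H, px = p / H;
        for (auto& d : nb) {
          const int qy = py + d.first, qx = px + d.second;
          if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
          if (mask(qy, qx) != 0 && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stackv.push_back(qy + H * qx);
          }
        }
      }
    }
  }
  return lab;
}

// Batch-normalization with per-channel statistics over the spatial
// positions of the given map.  Returns the output, the normalized map
// (cached for backward) and the per-channel inverse standard deviation.
// [[Rcpp::export]]
List cpp_bn_forward(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, double eps) {
  const arma::uword N = x.n_rows * x.n_cols, C = x.n_slices;
  arma::cube y(x.n_rows, x.n_cols, C), xhat(x.n_rows, x.n_cols, C);
  arma::vec istd(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xs = x.slice(c).memptr();
    double mu = 0, m2 = 0;
    for (arma::uword i = 0; i < N; ++i) mu += xs[i];
    mu /= N;
    for (arma::uword i = 0; i < N; ++i) {
      const double d = xs[i] - mu;
      m2 += d * d;
    }
    const double is = 1.0 / std::sqrt(m2 / N + eps);
    istd(c) = is;
    double* xh = xhat.slice(c).memptr();
    double* ys = y.slice(c).memptr();
    const double g = gamma(c), b = beta(c);
    for (arma::uword i = 0; i < N; ++i) {
      xh[i] = (xs[i] - mu) * is;
      ys[i] = g * xh[i] + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_bn_backward(const arma::cube& xhat, const arma::vec& istd,
                     const arma::vec& gamma, const arma::cube& dy) {
  const arma::uword N = dy.n_rows * dy.n_cols, C = dy.n_slices;
  arma::cube dx(dy.n_rows, dy.n_cols, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xh = xhat.slice(c).memptr();
    const double* g = dy.slice(c).memptr();
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    for (arma::uword i = 0; i < N; ++i) {
      dg += g[i] * xh[i];
      db += g[i];
    }
    dgamma(c) = dg; dbeta(c) = db;
    const double gam = gamma(c);
    s1 = gam * db; s2 = gam * dg;
    double* o = dx.slice(c).memptr();
    const double is = istd(c);
    for (arma::uword i = 0; i < N; ++i)
      o[i] = (gam * g[i] - s1 / N - xh[i] * s2 / N) * is;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::cube cpp_relu(const arma::cube& x) {
  arma::cube y = x;
  y.transform([](double v) { return v < 0 ? 0.0 : v; });
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_relu_backward(const arma::cube& dy, const arma::cube& y) {
  arma::cube dx = dy;
  const double* ys = y.memptr();
  double* d = dx.memptr();
  const arma::uword n = y.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (ys[i] <= 0) d[i] = 0;
  return dx;
}
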