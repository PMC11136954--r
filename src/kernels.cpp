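// Low-level numerical kernels for the segmentation network.
//
// Tensor layout convention (everywhere in this package):
//   activations  [H, W, C, N]   (column-major; H fastest)
//   conv weights [kh, kw, Cin, Cout]
// Convolutions are computed by im2col + GEMM per sample. The column matrix
// row ordering (ki fastest, then kj, then c) matches the column-major
// flattening of the weight array, so the weight can be used as a
// (kh*kw*Cin) x Cout matrix without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Fill `cols` (kh*kw*C x Ho*Wo) from one sample (H x W x C block at `x`).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, arma::mat& cols) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int wj = oj * sw - pw + kj * dw;
          double* col = cols.colptr(0) + r; // row r, walk columns manually
          if (wj < 0 || wj >= W) {
            for (int oi = 0; oi < Ho; ++oi)
              cols(r, oi + (size_t)oj * Ho) = 0.0;
            continue;
          }
          for (int oi = 0; oi < Ho; ++oi) {
            const int wi = oi * sh - ph + ki * dh;
            cols(r, oi + (size_t)oj * Ho) =
              (wi < 0 || wi >= H) ? 0.0 : xc[wi + (size_t)wj * H];
          }
          (void)col;
        }
      }
    }
  }
}

// Scatter-add the column matrix back into one sample (col2im).
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, double* dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int wj = oj * sw - pw + kj * dw;
          if (wj < 0 || wj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int wi = oi * sh - ph + ki * dh;
            if (wi < 0 || wi >= H) continue;
            xc[wi + (size_t)wj * H] += cols(r, oi + (size_t)oj * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias,
                             int sh, int sw, int ph, int pw,
                             int dh, int dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], O = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  const int Ho = out_size(H, kh, sh, ph, dh), Wo = out_size(W, kw, sw, pw, dw);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int K = kh * kw * C, Q = Ho * Wo;

  NumericVector y(no_init(Q * (size_t)O * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, O, false, true);
  const bool has_bias = bias.size() == O;
  const bool pointwise = (kh == 1 && kw == 1 && sh == 1 && sw == 1 &&
                          ph == 0 && pw == 0);
  arma::mat cols;
  if (!pointwise) cols.set_size(K, Q);

  for (int n = 0; n < N; ++n) {
    arma::mat Yn(y.begin() + (size_t)n * Q * O, Q, O, false, true);
    if (pointwise) {
      // 1x1 conv: the input block is already the column matrix
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                   Q, C, false, true);
      Yn = Xn * Wm;
    } else {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
             kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, cols);
      Yn = cols.t() * Wm;
    }
    if (has_bias)
      for (int o = 0; o < O; ++o) Yn.col(o) += bias[o];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_input_cpp(NumericVector dy, NumericVector w,
                                   int H, int W,
                                   int sh, int sw, int ph, int pw,
                                   int dh, int dw) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int Ho = yd[0], Wo = yd[1], O = yd[2], N = yd[3];
  const int kh = wd[0], kw = wd[1], C = wd[2];
  if (wd[3] != O) stop("conv2d backward: channel mismatch");
  const int K = kh * kw * C, Q = Ho * Wo;
  const bool pointwise = (kh == 1 && kw == 1 && sh == 1 && sw == 1 &&
                          ph == 0 && pw == 0 && Ho == H && Wo == W);

  NumericVector dx = pointwise
    ? NumericVector(no_init((size_t)H * W * C * N))
    : NumericVector((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, O, false, true);

  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * Q * O,
                  Q, O, false, true);
    if (pointwise) {
      arma::mat dXn(dx.begin() + (size_t)n * Q * C, Q, C, false, true);
      dXn = dYn * Wm.t();
    } else {
      arma::mat cols = Wm * dYn.t(); // K x Q
      col2im(cols, H, W, C, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
             dx.begin() + (size_t)n * H * W * C);
    }
  }
  return dx;
}

// [[Rcpp::export]]
List conv2d_bwd_weight_cpp(NumericVector x, NumericVector dy,
                           int kh, int kw,
                           int sh, int sw, int ph, int pw,
                           int dh, int dw) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], O = yd[2];
  const int K = kh * kw * C, Q = Ho * Wo;

  NumericVector dwt((size_t)K * O), db(O);
  dwt.attr("dim") = IntegerVector::create(kh, kw, C, O);
  arma::mat dWm(dwt.begin(), K, O, false, true);
  arma::vec dbv(db.begin(), O, false, true);
  const bool pointwise = (kh == 1 && kw == 1 && sh == 1 && sw == 1 &&
                          ph == 0 && pw == 0 && Ho == H && Wo == W);
  arma::mat cols;
  if (!pointwise) cols.set_size(K, Q);

  for (int n = 0; n < N; ++n) {
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * Q * O,
                  Q, O, false, true);
    if (pointwise) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * Q * C,
                   Q, C, false, true);
      dWm += Xn.t() * dYn;
    } else {
      im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
             kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, cols);
      dWm += cols * dYn;
    }
    dbv += arma::sum(dYn, 0).t();
  }
  return List::create(_["dw"] = dwt, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// linear indices into the input array (for the backward scatter).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          size_t best = base + (size_t)(2 * oj) * H + 2 * oi;
          double bv = x[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          // column-major write order matches oi-fastest loop only if we
          // compute the destination index explicitly:
          size_t dst = ((size_t)n * C + c) * Ho * Wo + (size_t)oj * Ho + oi;
          y[dst] = bv;
          idx[dst] = (int)(best + 1);
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(IntegerVector idx, NumericVector dy,
                               int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Non-overlapping k x k average pooling (H, W divisible by k).
// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % k || W % k) stop("avgpool: H and W must be divisible by k");
  const int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          double s = 0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              s += x[bi + (size_t)(oj * k + dj) * H + oi * k + di];
          y[bo + (size_t)oj * Ho + oi] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(NumericVector dy, int k, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int oj = 0; oj < Wo; ++oj)
        for (int oi = 0; oi < Ho; ++oi) {
          const double g = dy[bo + (size_t)oj * Ho + oi] * inv;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              dx[bi + (size_t)(oj * k + dj) * H + oi * k + di] += g;
        }
    }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample_nearest2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          y[bo + (size_t)j * Ho + i] = x[bi + (size_t)(j / 2) * H + i / 2];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_nearest2_bwd_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          dx[bi + (size_t)(j / 2) * H + i / 2] += dy[bo + (size_t)j * Ho + i];
    }
  return dx;
}

// Bilinear resize (half-pixel centres, like align_corners = FALSE).
// Returns the resized map; the backward pass reuses the same sample
// weights, so they are recomputed there rather than stored.
static inline void bilin_coef(int out, int in, int o, int& i0, int& i1,
                              double& w0, double& w1) {
  double src = (o + 0.5) * ((double)in / out) - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, in - 1);
  w1 = src - i0;
  w0 = 1.0 - w1;
}

// [[Rcpp::export]]
NumericVector upsample_bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        int j0, j1; double wj0, wj1;
        bilin_coef(Wo, W, j, j0, j1, wj0, wj1);
        for (int i = 0; i < Ho; ++i) {
          int i0, i1; double wi0, wi1;
          bilin_coef(Ho, H, i, i0, i1, wi0, wi1);
          y[bo + (size_t)j * Ho + i] =
            wi0 * wj0 * x[bi + (size_t)j0 * H + i0] +
            wi1 * wj0 * x[bi + (size_t)j0 * H + i1] +
            wi0 * wj1 * x[bi + (size_t)j1 * H + i0] +
            wi1 * wj1 * x[bi + (size_t)j1 * H + i1];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        int j0, j1; double wj0, wj1;
        bilin_coef(Wo, W, j, j0, j1, wj0, wj1);
        for (int i = 0; i < Ho; ++i) {
          int i0, i1; double wi0, wi1;
          bilin_coef(Ho, H, i, i0, i1, wi0, wi1);
          const double g = dy[bo + (size_t)j * Ho + i];
          dx[bi + (size_t)j0 * H + i0] += wi0 * wj0 * g;
          dx[bi + (size_t)j0 * H + i1] += wi1 * wj0 * g;
          dx[bi + (size_t)j1 * H + i0] += wi0 * wj1 * g;
          dx[bi + (size_t)j1 * H + i1] += wi1 * wj1 * g;
        }
      }
    }
  return dx;
}

// Fused PSA adaption + attention-crop. The over-complete map would hold
// (2H-1)(2W-1) channels per position, but each attention entry a_{i,j}
// reads exactly one of them: a_{i,j} = <x_i, W[, ch(i,j)]> + b[ch(i,j)],
// with x_i the reduced C2-vector at position i. Computing the dot products
// directly skips materializing the over-complete tensor.
// x: [H,W,C2,N]; w: C2 x Ch (the 1x1 adaption kernel); b: length Ch or 0;
// ch0: HW x HW 0-based channel indices. Returns A [HW, HW, N].
// [[Rcpp::export]]
NumericVector psa_attn_fused_fwd_cpp(NumericVector x, NumericVector w,
                                     NumericVector b, IntegerMatrix ch0) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  IntegerVector wd = w.attr("dim");
  const int Ch = wd[3];
  const bool has_b = b.size() == Ch;
  NumericVector A(no_init((size_t)HW * HW * N));
  A.attr("dim") = IntegerVector::create(HW, HW, N);
  std::vector<double> xt((size_t)C * HW);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    for (int p = 0; p < HW; ++p)          // transpose to position-major
      for (int c = 0; c < C; ++c)
        xt[(size_t)p * C + c] = xn[(size_t)c * HW + p];
    double* An = A.begin() + (size_t)n * HW * HW;
    for (int j = 0; j < HW; ++j)
      for (int i = 0; i < HW; ++i) {
        const int ch = ch0(i, j);
        const double* wc = w.begin() + (size_t)ch * C;
        const double* xi = &xt[(size_t)i * C];
        double s = has_b ? b[ch] : 0.0;
        for (int c = 0; c < C; ++c) s += xi[c] * wc[c];
        An[(size_t)j * HW + i] = s;
      }
  }
  return A;
}

// Backward of the fused op: returns dx [H,W,C2,N], dw (C2 x Ch), db (Ch).
// [[Rcpp::export]]
List psa_attn_fused_bwd_cpp(NumericVector x, NumericVector w,
                            NumericVector dA, IntegerMatrix ch0,
                            bool need_dx) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  IntegerVector wd = w.attr("dim");
  const int Ch = wd[3];
  NumericVector dx((size_t)HW * C * N), dw((size_t)C * Ch), db(Ch);
  dx.attr("dim") = xd;
  dw.attr("dim") = IntegerVector::create(1, 1, C, Ch);
  std::vector<double> xt((size_t)C * HW), dxt((size_t)C * HW);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    for (int p = 0; p < HW; ++p)
      for (int c = 0; c < C; ++c)
        xt[(size_t)p * C + c] = xn[(size_t)c * HW + p];
    std::fill(dxt.begin(), dxt.end(), 0.0);
    const double* dAn = dA.begin() + (size_t)n * HW * HW;
    for (int j = 0; j < HW; ++j)
      for (int i = 0; i < HW; ++i) {
        const double g = dAn[(size_t)j * HW + i];
        if (g == 0.0) continue;
        const int ch = ch0(i, j);
        const double* wc = w.begin() + (size_t)ch * C;
        double* dwc = dw.begin() + (size_t)ch * C;
        const double* xi = &xt[(size_t)i * C];
        double* dxi = &dxt[(size_t)i * C];
        for (int c = 0; c < C; ++c) {
          dwc[c] += g * xi[c];
          if (need_dx) dxi[c] += g * wc[c];
        }
        db[ch] += g;
      }
    if (need_dx) {
      double* dxn = dx.begin() + (size_t)n * HW * C;
      for (int p = 0; p < HW; ++p)
        for (int c = 0; c < C; ++c)
          dxn[(size_t)c * HW + p] = dxt[(size_t)p * C + c];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Confusion-matrix accumulation: pred/target are 0-based class vectors of
// equal length; entries equal to `ignore` (or < 0) are skipped.
// [[Rcpp::export]]
NumericMatrix confusion_accumulate_cpp(NumericMatrix cm0, IntegerVector target,
                                       IntegerVector pred, int ignore) {
  NumericMatrix cm = clone(cm0);
  const int K = cm.nrow();
  for (R_xlen_t i = 0; i < target.size(); ++i) {
    const int t = target[i], p = pred[i];
    if (t == ignore) continue;
    if (t < 0 || t >= K || p < 0 || p >= K)
      stop("class index out of range at pixel %ld (target %d, pred %d)",
           (long)(i + 1), t, p);
    cm(t, p) += 1.0;
  }
  return cm;
}
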