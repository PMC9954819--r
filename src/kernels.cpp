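// GEMM-based network kernels: 2D convolution (same padding, im2col),
// 2x2 max pooling with a floor convention (a height of 1 passes through
// unchanged), nearest-neighbour resizing, and LSTM forward/backward.
//
// Activation tensors use the layout (H, W, C, N); LSTM sequences use
// (N, F, T). All arithmetic is double precision. im2col matrices are
// rebuilt in the backward pass instead of cached, trading FLOPs for a
// flat memory footprint.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double actApply(double v, int act) {
  if (act == 1) return v > 0.0 ? v : 0.0;            // relu
  if (act == 2) return 1.0 / (1.0 + std::exp(-v));   // sigmoid
  return v;                                          // linear
}

// derivative of the activation expressed through the *output* y
static inline double actDerivFromOut(double y, int act) {
  if (act == 1) return y > 0.0 ? 1.0 : 0.0;
  if (act == 2) return y * (1.0 - y);
  return 1.0;
}

// The im2col column for kernel offset (oi, oj) is the input plane
// shifted by a single flat offset oi + H*oj; padding reduces to zeroing
// the spilled height-border rows and the flat range ends. This keeps the
// inner work one long memcpy per column instead of W short copies.
static void im2col(const double* xs, int H, int W, int C, int K,
                   arma::mat& colT) {
  const int P = K / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + HW * c;
    for (int dj = 0; dj < K; ++dj) {
      const int oj = dj - P;
      for (int di = 0; di < K; ++di) {
        const int oi = di - P;
        const int q = c * K * K + dj * K + di;
        double* col = colT.colptr(q);
        const long shift = oi + (long)H * oj;
        const size_t p0 = shift < 0 ? (size_t)(-shift) : 0;
        const size_t p1 = shift > 0 ? HW - shift : HW;   // copy [p0, p1)
        std::memset(col, 0, p0 * sizeof(double));
        std::memcpy(col + p0, xc + p0 + shift, (p1 - p0) * sizeof(double));
        std::memset(col + p1, 0, (HW - p1) * sizeof(double));
        // zero height-border rows that wrapped across columns
        for (int r = 0; r < oi; ++r)        // oi > 0: rows H-oi .. H-1
          for (size_t j = 0; j < (size_t)W; ++j) col[j * H + H - 1 - r] = 0.0;
        for (int r = 0; r < -oi; ++r)       // oi < 0: rows 0 .. -oi-1
          for (size_t j = 0; j < (size_t)W; ++j) col[j * H + r] = 0.0;
      }
    }
  }
}

static void col2imAdd(arma::mat& dcolT, int H, int W, int C, int K,
                      double* dxs) {
  const int P = K / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* dxc = dxs + HW * c;
    for (int dj = 0; dj < K; ++dj) {
      const int oj = dj - P;
      for (int di = 0; di < K; ++di) {
        const int oi = di - P;
        const int q = c * K * K + dj * K + di;
        double* col = dcolT.colptr(q);
        // discard gradient landing on padding before the shifted add
        for (int r = 0; r < oi; ++r)
          for (size_t j = 0; j < (size_t)W; ++j) col[j * H + H - 1 - r] = 0.0;
        for (int r = 0; r < -oi; ++r)
          for (size_t j = 0; j < (size_t)W; ++j) col[j * H + r] = 0.0;
        const long shift = oi + (long)H * oj;
        const size_t p0 = shift < 0 ? (size_t)(-shift) : 0;
        const size_t p1 = shift > 0 ? HW - shift : HW;
        double* dst = dxc + shift;
        for (size_t p = p0; p < p1; ++p) dst[p] += col[p];
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dFwd")]]
NumericVector conv2dFwd(NumericVector x, IntegerVector xdim,
                        NumericMatrix w, NumericVector b, int act) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int CKK = w.nrow(), Cout = w.ncol();
  const int K = (int)std::lround(std::sqrt((double)(CKK / C)));
  arma::mat Wm(w.begin(), CKK, Cout, false);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat colT(H * W, CKK);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    im2col(xs, H, W, C, K, colT);
    arma::mat Y = colT * Wm;                  // (HW) x Cout
    double* ys = y.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      const double* src = Y.colptr(co);
      double* dst = ys + (size_t)co * H * W;
      for (int p = 0; p < H * W; ++p) dst[p] = actApply(src[p] + bias, act);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2dBwd(NumericVector x, IntegerVector xdim, NumericMatrix w,
               NumericVector y, NumericVector dy, int act) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int CKK = w.nrow(), Cout = w.ncol();
  const int K = (int)std::lround(std::sqrt((double)(CKK / C)));
  arma::mat Wm(w.begin(), CKK, Cout, false);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  arma::mat dW(CKK, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat colT(H * W, CKK);
  arma::mat dpre(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    const double* ys = y.begin() + (size_t)n * H * W * Cout;
    const double* dys = dy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* dst = dpre.colptr(co);
      const double* yc = ys + (size_t)co * H * W;
      const double* dc = dys + (size_t)co * H * W;
      for (int p = 0; p < H * W; ++p)
        dst[p] = dc[p] * actDerivFromOut(yc[p], act);
    }
    im2col(xs, H, W, C, K, colT);
    dW += colT.t() * dpre;
    db += arma::sum(dpre, 0);
    arma::mat dcolT = dpre * Wm.t();          // (HW) x CKK
    col2imAdd(dcolT, H, W, C, K, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpoolFwd")]]
List maxpoolFwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int wh = H >= 2 ? 2 : 1;
  const int Ho = H >= 2 ? H / 2 : 1;
  const int Wo = W / 2;
  if (Wo < 1) stop("maxpool: time axis collapsed to zero");
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * Ho * Wo * C;
    int* is = idx.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * H * W;
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = 0;
          for (int j = oj * 2; j < oj * 2 + 2; ++j) {
            for (int i = oi * wh; i < oi * wh + wh; ++i) {
              const double v = xc[(size_t)j * H + i];
              if (v > best) { best = v; bidx = i + H * (j + W * c); }
            }
          }
          ys[oi + Ho * (oj + Wo * c)] = best;
          is[oi + Ho * (oj + Wo * c)] = bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpoolBwd")]]
NumericVector maxpoolBwd(IntegerVector idx, NumericVector dy,
                         IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = dy.attr("dim");
  const size_t perOut = (size_t)ydim[0] * ydim[1] * ydim[2];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + (size_t)n * perOut;
    const int* is = idx.begin() + (size_t)n * perOut;
    double* dxs = dx.begin() + (size_t)n * H * W * C;
    for (size_t p = 0; p < perOut; ++p) dxs[is[p]] += dys[p];
  }
  return dx;
}

// [[Rcpp::export(name = ".resizeNearestFwd")]]
NumericVector resizeNearestFwd(NumericVector x, IntegerVector xdim,
                               int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> mi(Ho), mj(Wo);
  for (int i = 0; i < Ho; ++i) mi[i] = (int)((long long)i * H / Ho);
  for (int j = 0; j < Wo; ++j) mj[j] = (int)((long long)j * W / Wo);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * H * W;
      double* yc = ys + (size_t)c * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        const double* sc = xc + (size_t)mj[j] * H;
        double* dc = yc + (size_t)j * Ho;
        if (Ho == H) std::memcpy(dc, sc, H * sizeof(double));
        else for (int i = 0; i < Ho; ++i) dc[i] = sc[mi[i]];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".resizeNearestBwd")]]
NumericVector resizeNearestBwd(NumericVector dy, IntegerVector ydim,
                               int H, int W) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> mi(Ho), mj(Wo);
  for (int i = 0; i < Ho; ++i) mi[i] = (int)((long long)i * H / Ho);
  for (int j = 0; j < Wo; ++j) mj[j] = (int)((long long)j * W / Wo);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + (size_t)n * Ho * Wo * C;
    double* dxs = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* dyc = dys + (size_t)c * Ho * Wo;
      double* dxc = dxs + (size_t)c * H * W;
      for (int j = 0; j < Wo; ++j) {
        const double* sc = dyc + (size_t)j * Ho;
        double* dc = dxc + (size_t)mj[j] * H;
        for (int i = 0; i < Ho; ++i) dc[mi[i]] += sc[i];
      }
    }
  }
  return dx;
}

// Gate column order within the 4U-wide preactivation: [i | f | g | o].
// [[Rcpp::export(name = ".lstmFwd")]]
List lstmFwd(NumericVector x, IntegerVector xdim, NumericMatrix wx,
             NumericMatrix wh, NumericVector b) {
  const int N = xdim[0], F = xdim[1], T = xdim[2];
  const int U = wh.nrow();
  arma::cube X((double*)x.begin(), N, F, T, false);
  arma::mat Wx(wx.begin(), F, 4 * U, false);
  arma::mat Wh(wh.begin(), U, 4 * U, false);
  arma::rowvec bv(b.begin(), 4 * U);
  arma::cube Hs(N, U, T), Cs(N, U, T), G(N, 4 * U, T);
  arma::mat hprev(N, U, arma::fill::zeros), cprev(N, U, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat Z = X.slice(t) * Wx + hprev * Wh;
    Z.each_row() += bv;
    arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.cols(0, U - 1)));
    arma::mat gf = 1.0 / (1.0 + arma::exp(-Z.cols(U, 2 * U - 1)));
    arma::mat gg = arma::tanh(Z.cols(2 * U, 3 * U - 1));
    arma::mat go = 1.0 / (1.0 + arma::exp(-Z.cols(3 * U, 4 * U - 1)));
    arma::mat c = gf % cprev + gi % gg;
    arma::mat h = go % arma::tanh(c);
    G.slice(t).cols(0, U - 1) = gi;
    G.slice(t).cols(U, 2 * U - 1) = gf;
    G.slice(t).cols(2 * U, 3 * U - 1) = gg;
    G.slice(t).cols(3 * U, 4 * U - 1) = go;
    Cs.slice(t) = c;
    Hs.slice(t) = h;
    hprev = h;
    cprev = c;
  }
  auto asArr = [&](arma::cube& cb, int d2) {
    NumericVector out(cb.begin(), cb.end());
    out.attr("dim") = IntegerVector::create(N, d2, T);
    return out;
  };
  return List::create(_["h"] = asArr(Hs, U), _["c"] = asArr(Cs, U),
                      _["g"] = asArr(G, 4 * U));
}

// [[Rcpp::export(name = ".lstmBwd")]]
List lstmBwd(NumericVector x, IntegerVector xdim, NumericMatrix wx,
             NumericMatrix wh, NumericVector g, NumericVector cs,
             NumericVector hs, NumericVector dhAll) {
  const int N = xdim[0], F = xdim[1], T = xdim[2];
  const int U = wh.nrow();
  arma::cube X((double*)x.begin(), N, F, T, false);
  arma::cube G((double*)g.begin(), N, 4 * U, T, false);
  arma::cube Cs((double*)cs.begin(), N, U, T, false);
  arma::cube Hs((double*)hs.begin(), N, U, T, false);
  arma::cube dH((double*)dhAll.begin(), N, U, T, false);
  arma::mat Wx(wx.begin(), F, 4 * U, false);
  arma::mat Wh(wh.begin(), U, 4 * U, false);
  arma::cube dX(N, F, T, arma::fill::zeros);
  arma::mat dWx(F, 4 * U, arma::fill::zeros);
  arma::mat dWh(U, 4 * U, arma::fill::zeros);
  arma::rowvec db(4 * U, arma::fill::zeros);
  arma::mat dhNext(N, U, arma::fill::zeros), dcNext(N, U, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat gi = G.slice(t).cols(0, U - 1);
    arma::mat gf = G.slice(t).cols(U, 2 * U - 1);
    arma::mat gg = G.slice(t).cols(2 * U, 3 * U - 1);
    arma::mat go = G.slice(t).cols(3 * U, 4 * U - 1);
    arma::mat cPrev = t > 0 ? Cs.slice(t - 1)
                            : arma::mat(N, U, arma::fill::zeros);
    arma::mat hPrev = t > 0 ? Hs.slice(t - 1)
                            : arma::mat(N, U, arma::fill::zeros);
    arma::mat tc = arma::tanh(Cs.slice(t));
    arma::mat dh = dH.slice(t) + dhNext;
    arma::mat dc = dh % go % (1.0 - tc % tc) + dcNext;
    arma::mat dZ(N, 4 * U);
    dZ.cols(0, U - 1) = (dc % gg) % gi % (1.0 - gi);
    dZ.cols(U, 2 * U - 1) = (dc % cPrev) % gf % (1.0 - gf);
    dZ.cols(2 * U, 3 * U - 1) = (dc % gi) % (1.0 - gg % gg);
    dZ.cols(3 * U, 4 * U - 1) = (dh % tc) % go % (1.0 - go);
    dWx += X.slice(t).t() * dZ;
    dWh += hPrev.t() * dZ;
    db += arma::sum(dZ, 0);
    dX.slice(t) = dZ * Wx.t();
    dhNext = dZ * Wh.t();
    dcNext = dc % gf;
  }
  NumericVector dx(dX.begin(), dX.end());
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dWx"] = wrap(dWx),
                      _["dWh"] = wrap(dWh),
                      _["db"] = NumericVector(db.begin(), db.end()));
}
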