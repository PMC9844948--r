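#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Inverse-mapping bilinear sampler shared by mouth-crop resizing and the
// augmentation affine warp. `M` is a 2x3 matrix mapping output pixel-center
// coordinates (x_out, y_out, 1) to input coordinates; pixels are 0-based,
// x right / y down, coordinates refer to pixel centers. Samples falling
// outside the input blend toward `fill` (constant border).
// [[Rcpp::export]]
NumericMatrix warp_bilinear_cpp(NumericMatrix img, NumericMatrix M,
                                int out_h, int out_w, double fill) {
  if (M.nrow() != 2 || M.ncol() != 3) stop("M must be 2x3");
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  for (int r = 0; r < out_h; ++r) {
    for (int c = 0; c < out_w; ++c) {
      double xo = c, yo = r;
      double xi = m00 * xo + m01 * yo + m02;
      double yi = m10 * xo + m11 * yo + m12;
      double x0 = std::floor(xi), y0 = std::floor(yi);
      double fx = xi - x0, fy = yi - y0;
      int ix0 = (int)x0, iy0 = (int)y0;
      double v = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = ix0 + dx, yy = iy0 + dy;
          double wgt = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy);
          double px = (xx >= 0 && xx < W && yy >= 0 && yy < H) ? img(yy, xx)
                                                               : fill;
          v += wgt * px;
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}

static inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

// Spatial max pooling over (H,W) with window = stride = (ph,pw); the time
// axis is untouched. Returns pooled values plus 0-based argmax indices into
// the input vector for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector pool) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], T = xd[1], H = xd[2], W = xd[3], C = xd[4];
  int ph = pool[0], pw = pool[1];
  int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1) stop("pool window larger than input");
  NumericVector y((R_xlen_t)N * T * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(N, T, Ho, Wo, C);
  NumericVector amax(y.size());
  amax.attr("dim") = y.attr("dim");
  const double *X = x.begin();
  double *Y = y.begin(), *A = amax.begin();
  for (int c = 0; c < C; ++c)
  for (int wo = 0; wo < Wo; ++wo)
  for (int ho = 0; ho < Ho; ++ho)
  for (int t = 0; t < T; ++t)
  for (int n = 0; n < N; ++n) {
    double best = R_NegInf; R_xlen_t besti = 0;
    for (int dh = 0; dh < ph; ++dh)
    for (int dw = 0; dw < pw; ++dw) {
      int hi = ho * ph + dh, wi = wo * pw + dw;
      R_xlen_t xi = n + (R_xlen_t)N * (t + (R_xlen_t)T *
                    (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c)));
      if (X[xi] > best) { best = X[xi]; besti = xi; }
    }
    R_xlen_t yi = n + (R_xlen_t)N * (t + (R_xlen_t)T *
                  (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c)));
    Y[yi] = best;
    A[yi] = (double)besti;
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, NumericVector argmax,
                              IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  const double *DY = dy.begin(), *A = argmax.begin();
  double *DX = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) DX[(R_xlen_t)A[i]] += DY[i];
  return dx;
}

// ---- fused 3D convolution (temporal stride 1, "same" padding) ----------
//
// The convolution is decomposed as a spatial patch unfold shared by all
// temporal taps, followed by one GEMM per temporal offset on contiguous
// row blocks (rows are ordered n, ho, wo, t with t slowest, so a temporal
// shift is a contiguous block handled directly by BLAS).

static void spatial_im2col(const double *X, int N, int T, int H, int W,
                           int C, int kh, int kw, int sh, int sw,
                           int Ho, int Wo, int ph, int pw, double *P) {
  // P: (N*Ho*Wo*T) x (kh*kw*C), row = n + N*(ho + Ho*(wo + Wo*t))
  R_xlen_t Rrows = (R_xlen_t)N * Ho * Wo * T;
  for (int c = 0; c < C; ++c)
  for (int dw = 0; dw < kw; ++dw)
  for (int dh = 0; dh < kh; ++dh) {
    R_xlen_t pcol = dh + (R_xlen_t)kh * (dw + (R_xlen_t)kw * c);
    double *col = P + pcol * Rrows;
    for (int t = 0; t < T; ++t)
    for (int wo = 0; wo < Wo; ++wo) {
      int wi = wo * sw - pw + dw;
      for (int ho = 0; ho < Ho; ++ho) {
        int hi = ho * sh - ph + dh;
        R_xlen_t r = (R_xlen_t)N * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * t));
        if (wi < 0 || wi >= W || hi < 0 || hi >= H) {
          for (int n = 0; n < N; ++n) col[r + n] = 0.0;
        } else {
          const double *src = X + (R_xlen_t)N * (t + (R_xlen_t)T *
                              (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c)));
          for (int n = 0; n < N; ++n) col[r + n] = src[n];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3d_fused_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                          IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int N = xd[0], T = xd[1], H = xd[2], W = xd[3], C = xd[4];
  int kt = wd[0], kh = wd[1], kw = wd[2], F = wd[4];
  int sh = stride[1], sw = stride[2];
  if (stride[0] != 1) stop("temporal stride must be 1");
  int Ho = ceil_div(H, sh), Wo = ceil_div(W, sw);
  int ph = std::max((Ho - 1) * sh + kh - H, 0) / 2;
  int pw = std::max((Wo - 1) * sw + kw - W, 0) / 2;
  int pt = (kt - 1) / 2;
  R_xlen_t Rrows = (R_xlen_t)N * Ho * Wo * T;
  int K = kh * kw * C;
  NumericMatrix P(Rrows, K);
  spatial_im2col(x.begin(), N, T, H, W, C, kh, kw, sh, sw, Ho, Wo, ph, pw,
                 P.begin());
  // accumulator in (n,ho,wo,t) x F order
  std::vector<double> Yt((size_t)Rrows * F);
  for (int f = 0; f < F; ++f)
    std::fill(Yt.begin() + (size_t)f * Rrows,
              Yt.begin() + (size_t)(f + 1) * Rrows, b[f]);
  std::vector<double> Wdt((size_t)K * F);
  R_xlen_t blk = (R_xlen_t)N * Ho * Wo;
  for (int dt = 0; dt < kt; ++dt) {
    // weight slice for this temporal tap, (kh*kw*C) x F
    for (int f = 0; f < F; ++f)
      for (int k = 0; k < K; ++k) {
        int dh = k % kh, rem = k / kh, dw = rem % kw, c = rem / kw;
        Wdt[k + (size_t)K * f] =
          w[dt + (R_xlen_t)kt * (dh + (R_xlen_t)kh *
              (dw + (R_xlen_t)kw * (c + (R_xlen_t)C * f)))];
      }
    int to_lo = std::max(0, pt - dt);
    int to_hi = std::min(T, T + pt - dt);
    if (to_hi <= to_lo) continue;
    int m = (int)((R_xlen_t)(to_hi - to_lo) * blk);
    int t_in0 = to_lo - pt + dt;
    const double *A = P.begin() + (R_xlen_t)t_in0 * blk;
    double *Cm = Yt.data() + (R_xlen_t)to_lo * blk;
    double one = 1.0;
    int lda = (int)Rrows, ldc = (int)Rrows, kk = K, nn = F;
    F77_CALL(dgemm)("N", "N", &m, &nn, &kk, &one, A, &lda, Wdt.data(), &kk,
                    &one, Cm, &ldc FCONE FCONE);
  }
  // permute (n,ho,wo,t,f) -> (n,t,ho,wo,f)
  NumericVector y(Rrows * F);
  y.attr("dim") = IntegerVector::create(N, T, Ho, Wo, F);
  double *Y = y.begin();
  for (int f = 0; f < F; ++f)
  for (int t = 0; t < T; ++t)
  for (int wo = 0; wo < Wo; ++wo)
  for (int ho = 0; ho < Ho; ++ho) {
    const double *src = Yt.data() + (R_xlen_t)N * (ho + (R_xlen_t)Ho *
                        (wo + (R_xlen_t)Wo * (t + (R_xlen_t)T * f)));
    double *dst = Y + (R_xlen_t)N * (t + (R_xlen_t)T * (ho + (R_xlen_t)Ho *
                  (wo + (R_xlen_t)Wo * f)));
    std::copy(src, src + N, dst);
  }
  return List::create(_["y"] = y, _["P"] = P);
}

// [[Rcpp::export]]
List conv3d_fused_bwd_cpp(NumericMatrix P, NumericVector w, NumericVector dy,
                          IntegerVector xdim, IntegerVector stride) {
  IntegerVector wd = w.attr("dim");
  int N = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], C = xdim[4];
  int kt = wd[0], kh = wd[1], kw = wd[2], F = wd[4];
  int sh = stride[1], sw = stride[2];
  int Ho = ceil_div(H, sh), Wo = ceil_div(W, sw);
  int ph = std::max((Ho - 1) * sh + kh - H, 0) / 2;
  int pw = std::max((Wo - 1) * sw + kw - W, 0) / 2;
  int pt = (kt - 1) / 2;
  R_xlen_t Rrows = (R_xlen_t)N * Ho * Wo * T;
  int K = kh * kw * C;
  // permute dy (n,t,ho,wo,f) -> (n,ho,wo,t) x F
  std::vector<double> dYt((size_t)Rrows * F);
  const double *DY = dy.begin();
  for (int f = 0; f < F; ++f)
  for (int t = 0; t < T; ++t)
  for (int wo = 0; wo < Wo; ++wo)
  for (int ho = 0; ho < Ho; ++ho) {
    const double *src = DY + (R_xlen_t)N * (t + (R_xlen_t)T *
                        (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * f)));
    double *dst = dYt.data() + (R_xlen_t)N * (ho + (R_xlen_t)Ho *
                  (wo + (R_xlen_t)Wo * (t + (R_xlen_t)T * f)));
    std::copy(src, src + N, dst);
  }
  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    double s = 0.0;
    const double *col = dYt.data() + (size_t)f * Rrows;
    for (R_xlen_t i = 0; i < Rrows; ++i) s += col[i];
    db[f] = s;
  }
  NumericVector dw_(w.size());
  dw_.attr("dim") = wd;
  std::vector<double> dP((size_t)Rrows * K, 0.0);
  std::vector<double> dWdt((size_t)K * F);
  R_xlen_t blk = (R_xlen_t)N * Ho * Wo;
  for (int dt = 0; dt < kt; ++dt) {
    int to_lo = std::max(0, pt - dt);
    int to_hi = std::min(T, T + pt - dt);
    if (to_hi <= to_lo) continue;
    int m = (int)((R_xlen_t)(to_hi - to_lo) * blk);
    int t_in0 = to_lo - pt + dt;
    const double *A = P.begin() + (R_xlen_t)t_in0 * blk;       // m x K
    const double *G = dYt.data() + (R_xlen_t)to_lo * blk;      // m x F
    double one = 1.0, zero = 0.0;
    int lda = (int)Rrows, kk = K, nn = F;
    // dW_dt = A^T G
    F77_CALL(dgemm)("T", "N", &kk, &nn, &m, &one, A, &lda, G, &lda, &zero,
                    dWdt.data(), &kk FCONE FCONE);
    for (int f = 0; f < F; ++f)
      for (int k = 0; k < K; ++k) {
        int dh = k % kh, rem = k / kh, dw2 = rem % kw, c = rem / kw;
        dw_[dt + (R_xlen_t)kt * (dh + (R_xlen_t)kh *
            (dw2 + (R_xlen_t)kw * (c + (R_xlen_t)C * f)))] +=
          dWdt[k + (size_t)K * f];
      }
    // dP_block += G W_dt^T
    std::vector<double> Wdt((size_t)K * F);
    for (int f = 0; f < F; ++f)
      for (int k = 0; k < K; ++k) {
        int dh = k % kh, rem = k / kh, dw2 = rem % kw, c = rem / kw;
        Wdt[k + (size_t)K * f] =
          w[dt + (R_xlen_t)kt * (dh + (R_xlen_t)kh *
              (dw2 + (R_xlen_t)kw * (c + (R_xlen_t)C * f)))];
      }
    double *DPb = dP.data() + (R_xlen_t)t_in0 * blk;
    F77_CALL(dgemm)("N", "T", &m, &kk, &nn, &one, G, &lda, Wdt.data(), &kk,
                    &one, DPb, &lda FCONE FCONE);
  }
  // fold dP back onto the input (adjoint of spatial_im2col)
  NumericVector dx((R_xlen_t)N * T * H * W * C);
  dx.attr("dim") = xdim;
  double *DX = dx.begin();
  for (int c = 0; c < C; ++c)
  for (int dw2 = 0; dw2 < kw; ++dw2)
  for (int dh = 0; dh < kh; ++dh) {
    R_xlen_t pcol = dh + (R_xlen_t)kh * (dw2 + (R_xlen_t)kw * c);
    const double *col = dP.data() + pcol * Rrows;
    for (int t = 0; t < T; ++t)
    for (int wo = 0; wo < Wo; ++wo) {
      int wi = wo * sw - pw + dw2;
      if (wi < 0 || wi >= W) continue;
      for (int ho = 0; ho < Ho; ++ho) {
        int hi = ho * sh - ph + dh;
        if (hi < 0 || hi >= H) continue;
        R_xlen_t r = (R_xlen_t)N * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * t));
        double *dst = DX + (R_xlen_t)N * (t + (R_xlen_t)T *
                      (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * c)));
        for (int n = 0; n < N; ++n) dst[n] += col[r + n];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw_, _["db"] = db);
}

// Stack a list of equally-shaped arrays into a batch along a new first
// axis.
// [[Rcpp::export]]
NumericVector stack_arrays_cpp(List arrays) {
  int n = arrays.size();
  NumericVector first = arrays[0];
  IntegerVector d0 = first.attr("dim");
  R_xlen_t per = first.size();
  NumericVector out((R_xlen_t)n * per);
  IntegerVector nd(d0.size() + 1);
  nd[0] = n;
  for (int i = 0; i < d0.size(); ++i) nd[i + 1] = d0[i];
  out.attr("dim") = nd;
  double *O = out.begin();
  for (int i = 0; i < n; ++i) {
    NumericVector a = arrays[i];
    const double *A = a.begin();
    for (R_xlen_t j = 0; j < per; ++j) O[i + (R_xlen_t)n * j] = A[j];
  }
  return out;
}

// Affine-warp every frame of a (T,H,W) stack with one shared 2x3 matrix
// (inverse mapping, bilinear, constant fill). Frames beyond valid_length
// are constant fill and skipped.
// [[Rcpp::export]]
NumericVector warp_stack_cpp(NumericVector frames, NumericMatrix M,
                             double fill, int valid_length) {
  IntegerVector d = frames.attr("dim");
  int T = d[0], H = d[1], W = d[2];
  NumericVector out(frames.size());
  out.attr("dim") = d;
  const double *X = frames.begin();
  double *O = out.begin();
  double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  int tmax = std::min(T, valid_length);
  for (int c = 0; c < W; ++c)
  for (int r = 0; r < H; ++r) {
    double xi = m00 * c + m01 * r + m02;
    double yi = m10 * c + m11 * r + m12;
    double x0 = std::floor(xi), y0 = std::floor(yi);
    double fx = xi - x0, fy = yi - y0;
    int ix0 = (int)x0, iy0 = (int)y0;
    double wgt[4]; R_xlen_t off[4]; bool ok[4];
    int q = 0;
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx, ++q) {
        int xx = ix0 + dx, yy = iy0 + dy;
        wgt[q] = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy);
        ok[q] = (xx >= 0 && xx < W && yy >= 0 && yy < H);
        off[q] = ok[q] ? (R_xlen_t)T * (yy + (R_xlen_t)H * xx) : 0;
      }
    R_xlen_t dst = (R_xlen_t)T * (r + (R_xlen_t)H * c);
    for (int t = 0; t < tmax; ++t) {
      double v = 0.0;
      for (int q2 = 0; q2 < 4; ++q2)
        v += wgt[q2] * (ok[q2] ? X[off[q2] + t] : fill);
      O[dst + t] = v;
    }
    for (int t = tmax; t < T; ++t) O[dst + t] = fill;
  }
  return out;
}

// Spatial average pooling (window = stride), time axis untouched.
// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(NumericVector x, IntegerVector pool) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], T = xd[1], H = xd[2], W = xd[3], C = xd[4];
  int ph = pool[0], pw = pool[1];
  int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1) stop("pool window larger than input");
  NumericVector y((R_xlen_t)N * T * Ho * Wo * C);
  y.attr("dim") = IntegerVector::create(N, T, Ho, Wo, C);
  const double *X = x.begin();
  double *Y = y.begin();
  double inv = 1.0 / (ph * pw);
  R_xlen_t NT = (R_xlen_t)N * T;
  for (int c = 0; c < C; ++c)
  for (int wo = 0; wo < Wo; ++wo)
  for (int ho = 0; ho < Ho; ++ho) {
    double *dst = Y + NT * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c));
    for (R_xlen_t i = 0; i < NT; ++i) dst[i] = 0.0;
    for (int dh = 0; dh < ph; ++dh)
    for (int dw = 0; dw < pw; ++dw) {
      const double *src = X + NT * ((ho * ph + dh) + (R_xlen_t)H *
                          ((wo * pw + dw) + (R_xlen_t)W * c));
      for (R_xlen_t i = 0; i < NT; ++i) dst[i] += src[i];
    }
    for (R_xlen_t i = 0; i < NT; ++i) dst[i] *= inv;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(NumericVector dy, IntegerVector pool,
                              IntegerVector xdim) {
  int N = xdim[0], T = xdim[1], H = xdim[2], W = xdim[3], C = xdim[4];
  int ph = pool[0], pw = pool[1];
  int Ho = H / ph, Wo = W / pw;
  NumericVector dx((R_xlen_t)N * T * H * W * C);
  dx.attr("dim") = xdim;
  const double *DY = dy.begin();
  double *DX = dx.begin();
  double inv = 1.0 / (ph * pw);
  R_xlen_t NT = (R_xlen_t)N * T;
  for (int c = 0; c < C; ++c)
  for (int wo = 0; wo < Wo; ++wo)
  for (int ho = 0; ho < Ho; ++ho) {
    const double *src = DY + NT * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * c));
    for (int dh = 0; dh < ph; ++dh)
    for (int dw = 0; dw < pw; ++dw) {
      double *dst = DX + NT * ((ho * ph + dh) + (R_xlen_t)H *
                    ((wo * pw + dw) + (R_xlen_t)W * c));
      for (R_xlen_t i = 0; i < NT; ++i) dst[i] = src[i] * inv;
    }
  }
  return dx;
}

// Gaussian noise (R RNG) + brightness offset + clip to [-1,1], applied to
// the first valid_length frames of a (T,H,W) stack in one pass.
// [[Rcpp::export]]
NumericVector noise_brightness_clip_cpp(NumericVector frames, double sigma,
                                        double brightness, int valid_length) {
  IntegerVector d = frames.attr("dim");
  int T = d[0];
  NumericVector out = clone(frames);
  double *O = out.begin();
  R_xlen_t HW = out.size() / T;
  int tmax = std::min(T, valid_length);
  RNGScope scope;
  // Marsaglia polar method on R's uniform stream: exact Gaussians at a
  // fraction of the cost of the default inversion sampler
  double spare = 0.0; bool have_spare = false;
  for (R_xlen_t j = 0; j < HW; ++j) {
    double *colp = O + j * T;
    for (int t = 0; t < tmax; ++t) {
      double v = colp[t] + brightness;
      if (sigma > 0) {
        double g;
        if (have_spare) { g = spare; have_spare = false; }
        else {
          double u1, u2, s;
          do {
            u1 = 2.0 * unif_rand() - 1.0;
            u2 = 2.0 * unif_rand() - 1.0;
            s = u1 * u1 + u2 * u2;
          } while (s >= 1.0 || s == 0.0);
          double f = std::sqrt(-2.0 * std::log(s) / s);
          g = u1 * f; spare = u2 * f; have_spare = true;
        }
        v += g * sigma;
      }
      colp[t] = v < -1.0 ? -1.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  return out;
}

// ---- GRU forward / backward --------------------------------------------
//
// Convention: z = sigm(x Wz + h Uz + bz), r = sigm(x Wr + h Ur + br),
// hh = tanh(x Wh + (r*h) Uh + bh), h' = z*h + (1-z)*hh.
// Weights are packed (D x 3U) / (U x 3U) / (3U) in z, r, h order.

static inline double sigm(double v) { return 1.0 / (1.0 + std::exp(-v)); }

static void small_gemm(const char *ta, const char *tb, int m, int n, int k,
                       double alpha, const double *A, int lda,
                       const double *B, int ldb, double beta, double *C,
                       int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// [[Rcpp::export]]
List gru_fwd_cpp(NumericVector x, NumericMatrix w, NumericMatrix u,
                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], T = xd[1], D = xd[2];
  int U3 = u.ncol(), U = U3 / 3;
  // ax = X W + b for all timesteps: X viewed as (N*T) x D
  std::vector<double> ax((size_t)N * T * U3);
  small_gemm("N", "N", N * T, U3, D, 1.0, x.begin(), N * T, w.begin(), D,
             0.0, ax.data(), N * T);
  for (int j = 0; j < U3; ++j) {
    double bj = b[j];
    double *col = ax.data() + (size_t)j * N * T;
    for (int i = 0; i < N * T; ++i) col[i] += bj;
  }
  NumericVector h((R_xlen_t)N * T * U), zs(h.size()), rs(h.size()),
    hhs(h.size());
  IntegerVector hd = IntegerVector::create(N, T, U);
  h.attr("dim") = hd; zs.attr("dim") = hd; rs.attr("dim") = hd;
  hhs.attr("dim") = hd;
  std::vector<double> hprev((size_t)N * U, 0.0), ah((size_t)N * U3),
    rh((size_t)N * U);
  for (int t = 0; t < T; ++t) {
    // ah = hprev U  (N x 3U)
    small_gemm("N", "N", N, U3, U, 1.0, hprev.data(), N, u.begin(), U, 0.0,
               ah.data(), N);
    // gates
    for (int j = 0; j < U; ++j)
      for (int n = 0; n < N; ++n) {
        size_t axi = n + (size_t)N * (t + (size_t)T * j);
        double z = sigm(ax[axi] + ah[n + (size_t)N * j]);
        size_t axr = n + (size_t)N * (t + (size_t)T * (U + j));
        double r = sigm(ax[axr] + ah[n + (size_t)N * (U + j)]);
        zs[n + (R_xlen_t)N * (t + (R_xlen_t)T * j)] = z;
        rs[n + (R_xlen_t)N * (t + (R_xlen_t)T * j)] = r;
        rh[n + (size_t)N * j] = r * hprev[n + (size_t)N * j];
      }
    // candidate: ahh = x Wh (in ax) + (r*h) Uh
    std::vector<double> ahh((size_t)N * U);
    small_gemm("N", "N", N, U, U, 1.0, rh.data(), N,
               u.begin() + (size_t)U * 2 * U, U, 0.0, ahh.data(), N);
    for (int j = 0; j < U; ++j)
      for (int n = 0; n < N; ++n) {
        size_t axh = n + (size_t)N * (t + (size_t)T * (2 * U + j));
        double hh = std::tanh(ax[axh] + ahh[n + (size_t)N * j]);
        double z = zs[n + (R_xlen_t)N * (t + (R_xlen_t)T * j)];
        double hp = hprev[n + (size_t)N * j];
        double hnew = z * hp + (1.0 - z) * hh;
        hhs[n + (R_xlen_t)N * (t + (R_xlen_t)T * j)] = hh;
        h[n + (R_xlen_t)N * (t + (R_xlen_t)T * j)] = hnew;
        hprev[n + (size_t)N * j] = hnew;
      }
  }
  return List::create(_["h"] = h, _["z"] = zs, _["r"] = rs, _["hh"] = hhs);
}

// [[Rcpp::export]]
List gru_bwd_cpp(NumericVector x, NumericMatrix w, NumericMatrix u,
                 NumericVector h, NumericVector zs, NumericVector rs,
                 NumericVector hhs, NumericVector dh_all) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], T = xd[1], D = xd[2];
  int U3 = u.ncol(), U = U3 / 3;
  NumericMatrix dw(D, U3), du(U, U3);
  NumericVector db(U3);
  NumericVector dx((R_xlen_t)N * T * D);
  dx.attr("dim") = xd;
  std::vector<double> dhn((size_t)N * U, 0.0);
  std::vector<double> da((size_t)N * U3), hprev((size_t)N * U),
    rh((size_t)N * U), dtmp((size_t)N * U);
  // da for one timestep stored (N x 3U); accumulated into dw/du via GEMM
  std::vector<double> xt((size_t)N * D);
  for (int t = T - 1; t >= 0; --t) {
    for (int j = 0; j < U; ++j)
      for (int n = 0; n < N; ++n) {
        hprev[n + (size_t)N * j] =
          (t > 0) ? h[n + (R_xlen_t)N * ((t - 1) + (R_xlen_t)T * j)] : 0.0;
      }
    for (int j = 0; j < U; ++j)
      for (int n = 0; n < N; ++n) {
        size_t i = n + (size_t)N * j;
        R_xlen_t hi = n + (R_xlen_t)N * (t + (R_xlen_t)T * j);
        double dh = dh_all[hi] + dhn[i];
        double z = zs[hi], r = rs[hi], hh = hhs[hi], hp = hprev[i];
        double daz = dh * (hp - hh) * z * (1.0 - z);
        double dahh = dh * (1.0 - z) * (1.0 - hh * hh);
        da[i] = daz;                       // z block
        da[i + (size_t)N * 2 * U] = dahh;  // h block
        dhn[i] = dh * z;                   // dh_prev (accumulates below)
        rh[i] = r * hp;
      }
    // drh = dahh Uh^T ; dr = drh * hprev ; dh_prev += drh * r
    small_gemm("N", "T", N, U, U, 1.0, da.data() + (size_t)N * 2 * U, N,
               u.begin() + (size_t)U * 2 * U, U, 0.0, dtmp.data(), N);
    for (int j = 0; j < U; ++j)
      for (int n = 0; n < N; ++n) {
        size_t i = n + (size_t)N * j;
        R_xlen_t hi = n + (R_xlen_t)N * (t + (R_xlen_t)T * j);
        double r = rs[hi];
        double dr = dtmp[i] * hprev[i];
        da[i + (size_t)N * U] = dr * r * (1.0 - r);   // r block
        dhn[i] += dtmp[i] * r;
      }
    // dh_prev += daz Uz^T + dar Ur^T
    small_gemm("N", "T", N, U, U, 1.0, da.data(), N, u.begin(), U, 1.0,
               dhn.data(), N);
    small_gemm("N", "T", N, U, U, 1.0, da.data() + (size_t)N * U, N,
               u.begin() + (size_t)U * U, U, 1.0, dhn.data(), N);
    // weight gradients: dw += xt^T da ; du(z,r) += hprev^T da ; du(h) += rh^T dahh
    for (int d = 0; d < D; ++d)
      for (int n = 0; n < N; ++n)
        xt[n + (size_t)N * d] = x[n + (R_xlen_t)N * (t + (R_xlen_t)T * d)];
    small_gemm("T", "N", D, U3, N, 1.0, xt.data(), N, da.data(), N, 1.0,
               dw.begin(), D);
    small_gemm("T", "N", U, U, N, 1.0, hprev.data(), N, da.data(), N, 1.0,
               du.begin(), U);
    small_gemm("T", "N", U, U, N, 1.0, hprev.data(), N,
               da.data() + (size_t)N * U, N, 1.0, du.begin() + (size_t)U * U,
               U);
    small_gemm("T", "N", U, U, N, 1.0, rh.data(), N,
               da.data() + (size_t)N * 2 * U, N, 1.0,
               du.begin() + (size_t)U * 2 * U, U);
    for (int j = 0; j < U3; ++j) {
      double s = 0.0;
      for (int n = 0; n < N; ++n) s += da[n + (size_t)N * j];
      db[j] += s;
    }
    // dx_t = da W^T (xt doubles as an N x D buffer)
    small_gemm("N", "T", N, D, U3, 1.0, da.data(), N, w.begin(), D, 0.0,
               xt.data(), N);
    for (int d = 0; d < D; ++d)
      for (int n = 0; n < N; ++n)
        dx[n + (R_xlen_t)N * (t + (R_xlen_t)T * d)] = xt[n + (size_t)N * d];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["du"] = du, _["db"] = db);
}
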