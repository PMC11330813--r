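// Low-level numeric kernels: im2col convolution (forward + both backward
// passes), 2x2 max pooling, pixel-shuffle for 2x2 transposed convolution,
// nearest-neighbour upsampling, per-column affine transforms for batch
// normalisation, and geometric warping for augmentation.
//
// Tensor layout convention (shared with the R code): a feature map is a
// numeric matrix with N*H*W rows (sample index n fastest, then h, then w)
// and C columns, carrying its dims c(N, H, W, C) as an attribute on the R
// side.  Convolution weights are matrices of shape (k*k*Cin) x Cout whose
// row index is kh + k*kw + k*k*ci (kh fastest), matching the R flattening of
// an array with dim c(k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Set feature-map attributes (dim + "fmd") on a freshly allocated vector
// without copying it.  Only ever called on results this package just
// computed, so in-place modification is safe.
// [[Rcpp::export]]
SEXP cpp_set_fmd(SEXP x, IntegerVector dims) {
  SEXP dim = PROTECT(Rf_allocVector(INTSXP, 2));
  INTEGER(dim)[0] = dims[0] * dims[1] * dims[2];
  INTEGER(dim)[1] = dims[3];
  Rf_setAttrib(x, R_DimSymbol, dim);
  Rf_setAttrib(x, Rf_install("fmd"), dims);
  UNPROTECT(1);
  return x;
}

// Convolutions run their inner GEMM in single precision (the standard
// arithmetic for CNN training); inputs, weights and results stay double at
// the interface.  im2col fills a float patch matrix directly.
//
// For a fixed tap (kh, kw) the valid h-range is contiguous, so each target
// column is filled with one fill/copy pair per w.
static void im2col_fill(const double* x, int N, int H, int W, int C,
                        int k, int dil, int pad, arma::fmat& cols) {
  const std::size_t NH = (std::size_t)N * H;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + NH * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        float* dst = cols.colptr(kh + k * kw + k * k * ci);
        const int dh = dil * kh - pad, dw = dil * kw - pad;
        const int hlo = std::max(0, -dh), hhi = std::min(H - 1, H - 1 - dh);
        for (int w = 0; w < W; ++w) {
          const int ww = w + dw;
          float* dcol = dst + NH * w;
          if (ww < 0 || ww >= W || hlo > hhi) {
            std::fill(dcol, dcol + NH, 0.0f);
            continue;
          }
          if (hlo > 0) std::fill(dcol, dcol + (std::size_t)N * hlo, 0.0f);
          std::copy(xc + NH * ww + (std::size_t)N * (hlo + dh),
                    xc + NH * ww + (std::size_t)N * (hhi + dh + 1),
                    dcol + (std::size_t)N * hlo);
          if (hhi < H - 1) {
            std::fill(dcol + (std::size_t)N * (hhi + 1), dcol + NH, 0.0f);
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col_fill: dx += col2im(dcols).
static void col2im_add(const arma::fmat& dcols, int N, int H, int W, int C,
                       int k, int dil, int pad, double* dx) {
  const std::size_t NH = (std::size_t)N * H;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + NH * W * ci;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const float* src = dcols.colptr(kh + k * kw + k * k * ci);
        const int dh = dil * kh - pad, dw = dil * kw - pad;
        const int hlo = std::max(0, -dh), hhi = std::min(H - 1, H - 1 - dh);
        if (hlo > hhi) continue;
        for (int w = 0; w < W; ++w) {
          const int ww = w + dw;
          if (ww < 0 || ww >= W) continue;
          const float* s = src + NH * w + (std::size_t)N * hlo;
          double* d = xc + NH * ww + (std::size_t)N * (hlo + dh);
          const std::size_t len = (std::size_t)N * (hhi - hlo + 1);
          for (std::size_t i = 0; i < len; ++i) d[i] += s[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector bias,
                            int k, int dil, int pad) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = w.ncol();
  arma::fmat cols((std::size_t)N * H * W, (std::size_t)k * k * C);
  im2col_fill(x.begin(), N, H, W, C, k, dil, pad, cols);
  arma::fmat wm(w.nrow(), w.ncol());
  std::copy(w.begin(), w.end(), wm.begin());
  arma::fmat y = cols * wm;
  NumericVector out(y.n_elem);
  if (bias.size() == (R_xlen_t)Cout) {
    const std::size_t rows = y.n_rows;
    for (int c = 0; c < Cout; ++c) {
      const float* s = y.colptr(c);
      double* d = out.begin() + rows * c;
      const double b = bias[c];
      for (std::size_t i = 0; i < rows; ++i) d[i] = (double)s[i] + b;
    }
  } else {
    std::copy(y.begin(), y.end(), out.begin());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector dy, IntegerVector dims,
                   NumericMatrix w, int k, int dil, int pad) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Cout = w.ncol();
  const std::size_t rows = (std::size_t)N * H * W;
  arma::fmat wm(w.nrow(), w.ncol());
  std::copy(w.begin(), w.end(), wm.begin());
  arma::fmat dym(rows, Cout);
  std::copy(dy.begin(), dy.end(), dym.begin());

  arma::fmat cols(rows, (std::size_t)k * k * C);
  im2col_fill(x.begin(), N, H, W, C, k, dil, pad, cols);
  arma::fmat dwf = cols.t() * dym;
  NumericMatrix dw(w.nrow(), w.ncol());
  std::copy(dwf.begin(), dwf.end(), dw.begin());
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    double acc = 0;
    const double* s = dy.begin() + rows * c;
    for (std::size_t i = 0; i < rows; ++i) acc += s[i];
    db[c] = acc;
  }
  cols = dym * wm.t();  // reuse storage shape (rows x k*k*C)

  NumericVector dx(rows * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im_add(cols, N, H, W, C, k, dil, pad, dx.begin());

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with stride 2; also returns 1-based linear argmax indices
// into x so the backward pass is a plain scatter in R.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector dims) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)N * Ho * Wo * C);
  IntegerVector idx((std::size_t)N * Ho * Wo * C);
  const double* xp = x.begin();
  std::size_t o = 0;
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int n = 0; n < N; ++n) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const std::size_t ii = (std::size_t)n +
                (std::size_t)N * ((2 * ho + dh) +
                (std::size_t)H * ((2 * wo + dw) + (std::size_t)W * c));
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          }
          y[o] = best;
          idx[o] = (int)(bi + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Rearrange the GEMM output of a 2x2 stride-2 transposed convolution:
// ym is (N*H*W) x (4*Cout) with column index kh + 2*kw + 4*co; the result is
// the (N*2H*2W) x Cout matrix of the upsampled map.
// [[Rcpp::export]]
NumericVector cpp_pixelshuffle2_fw(NumericVector ym, IntegerVector dims,
                                   int cout) {
  const int N = dims[0], H = dims[1], W = dims[2];
  const std::size_t rows = (std::size_t)N * H * W;
  const std::size_t orow = rows * 4;
  NumericVector out(orow * cout);
  const double* yp = ym.begin();
  for (int co = 0; co < cout; ++co) {
    for (int kw = 0; kw < 2; ++kw) {
      for (int kh = 0; kh < 2; ++kh) {
        const double* src = yp + rows * (kh + 2 * kw + 4 * co);
        double* dst = out.begin() + orow * co;
        for (int w = 0; w < W; ++w) {
          for (int h = 0; h < H; ++h) {
            std::copy(src, src + N,
                      dst + (std::size_t)N * ((2 * h + kh) +
                            (std::size_t)2 * H * ((2 * w + kw))));
            src += N;
          }
          dst += 0;  // dst offset handled via expression above
        }
      }
    }
  }
  return out;
}

// Inverse gather: dy is (N*2H*2W) x Cout; returns (N*H*W) x (4*Cout).
// [[Rcpp::export]]
NumericVector cpp_pixelshuffle2_bw(NumericVector dy, IntegerVector dims,
                                   int cout) {
  const int N = dims[0], H = dims[1], W = dims[2];
  const std::size_t rows = (std::size_t)N * H * W;
  const std::size_t orow = rows * 4;
  NumericVector out(rows * 4 * cout);
  const double* gp = dy.begin();
  for (int co = 0; co < cout; ++co) {
    for (int kw = 0; kw < 2; ++kw) {
      for (int kh = 0; kh < 2; ++kh) {
        double* dst = out.begin() + rows * (kh + 2 * kw + 4 * co);
        const double* src = gp + orow * co;
        for (int w = 0; w < W; ++w) {
          for (int h = 0; h < H; ++h) {
            std::copy(src + (std::size_t)N * ((2 * h + kh) +
                            (std::size_t)2 * H * ((2 * w + kw))),
                      src + (std::size_t)N * ((2 * h + kh) +
                            (std::size_t)2 * H * ((2 * w + kw))) + N,
                      dst);
            dst += N;
          }
        }
      }
    }
  }
  return out;
}

// nearest-neighbour x2 upsampling: (N*H*W) x C -> (N*2H*2W) x C
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, IntegerVector dims) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const std::size_t rows = (std::size_t)N * H * W;
  NumericVector out(rows * 4 * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + rows * c;
    double* oc = op + rows * 4 * c;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* s = xc + (std::size_t)N * (h + (std::size_t)H * w);
        for (int kw = 0; kw < 2; ++kw) {
          for (int kh = 0; kh < 2; ++kh) {
            std::copy(s, s + N,
                      oc + (std::size_t)N * ((2 * h + kh) +
                           (std::size_t)2 * H * (2 * w + kw)));
          }
        }
      }
    }
  }
  return out;
}

// backward of nearest x2 upsampling: sum each 2x2 block
// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy, IntegerVector dims) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const std::size_t rows = (std::size_t)N * H * W;
  NumericVector out(rows * C);
  const double* gp = dy.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + rows * 4 * c;
    double* oc = op + rows * c;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* d = oc + (std::size_t)N * (h + (std::size_t)H * w);
        for (int n = 0; n < N; ++n) d[n] = 0.0;
        for (int kw = 0; kw < 2; ++kw) {
          for (int kh = 0; kh < 2; ++kh) {
            const double* s = gc + (std::size_t)N * ((2 * h + kh) +
                              (std::size_t)2 * H * (2 * w + kw));
            for (int n = 0; n < N; ++n) d[n] += s[n];
          }
        }
      }
    }
  }
  return out;
}

// per-column affine transform: out[i,j] = m[i,j] * a[j] + b[j]
// [[Rcpp::export]]
NumericVector cpp_col_affine(NumericVector m, int nrow, NumericVector a,
                             NumericVector b) {
  const int C = a.size();
  NumericVector out((std::size_t)nrow * C);
  const double* mp = m.begin();
  double* op = out.begin();
  for (int j = 0; j < C; ++j) {
    const double aj = a[j], bj = b[j];
    const double* s = mp + (std::size_t)nrow * j;
    double* d = op + (std::size_t)nrow * j;
    for (int i = 0; i < nrow; ++i) d[i] = s[i] * aj + bj;
  }
  return out;
}

// per-column mean and (biased) variance in one pass
// [[Rcpp::export]]
List cpp_col_meanvar(NumericVector m, int nrow) {
  const int C = (int)(m.size() / nrow);
  NumericVector mu(C), va(C);
  for (int j = 0; j < C; ++j) {
    const double* s = m.begin() + (std::size_t)nrow * j;
    double acc = 0, acc2 = 0;
    for (int i = 0; i < nrow; ++i) { acc += s[i]; acc2 += s[i] * s[i]; }
    mu[j] = acc / nrow;
    const double v = acc2 / nrow - mu[j] * mu[j];
    va[j] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// out = x * (x > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector out(x.size());
  const double* s = x.begin();
  double* d = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) d[i] = s[i] > 0 ? s[i] : 0.0;
  return out;
}

// out = g * (x > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector g, NumericVector x) {
  NumericVector out(g.size());
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* d = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) d[i] = xp[i] > 0 ? gp[i] : 0.0;
  return out;
}

// batch-norm input gradient (training mode):
// out[i,j] = (g[i,j] - dbeta[j]/m - xhat[i,j] * dgamma[j]/m) * gs[j]
// [[Rcpp::export]]
NumericVector cpp_bn_bw(NumericVector g, NumericVector xhat, int nrow,
                        NumericVector dbeta, NumericVector dgamma,
                        NumericVector gs) {
  const int C = dbeta.size();
  NumericVector out((std::size_t)nrow * C);
  const double* gp = g.begin();
  const double* xp = xhat.begin();
  double* op = out.begin();
  for (int j = 0; j < C; ++j) {
    const double b = dbeta[j] / nrow, dg = dgamma[j] / nrow, s = gs[j];
    const double* gj = gp + (std::size_t)nrow * j;
    const double* xj = xp + (std::size_t)nrow * j;
    double* d = op + (std::size_t)nrow * j;
    for (int i = 0; i < nrow; ++i) d[i] = (gj[i] - b - xj[i] * dg) * s;
  }
  return out;
}

// Geometric warp of a single-channel H x W image (R matrix, column-major,
// first index = row/y).  mapy/mapx give, for every target pixel, the source
// coordinate (1-based, real-valued).  method: 0 = nearest, 1 = bilinear.
// border: 0 = constant `fill`, 1 = reflect.
static inline double fetch(const double* img, int H, int W, int i, int j,
                           int border, double fill) {
  if (border == 1) {
    if (i < 0) i = -i; if (i >= H) i = 2 * H - 2 - i;
    if (j < 0) j = -j; if (j >= W) j = 2 * W - 2 - j;
    if (i < 0 || i >= H || j < 0 || j >= W) return fill;  // tiny images
  } else if (i < 0 || i >= H || j < 0 || j >= W) {
    return fill;
  }
  return img[i + (std::size_t)H * j];
}

// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, NumericMatrix mapy, NumericMatrix mapx,
                       int method, int border, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const int Ho = mapy.nrow(), Wo = mapy.ncol();
  NumericMatrix out(Ho, Wo);
  const double* ip = img.begin();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double sy = mapy(i, j) - 1.0;  // to 0-based
      const double sx = mapx(i, j) - 1.0;
      if (method == 0) {
        const int iy = (int)std::lround(sy);
        const int ix = (int)std::lround(sx);
        out(i, j) = fetch(ip, H, W, iy, ix, border, fill);
      } else {
        const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        const double fy = sy - y0, fx = sx - x0;
        const double v00 = fetch(ip, H, W, y0, x0, border, fill);
        const double v10 = fetch(ip, H, W, y0 + 1, x0, border, fill);
        const double v01 = fetch(ip, H, W, y0, x0 + 1, border, fill);
        const double v11 = fetch(ip, H, W, y0 + 1, x0 + 1, border, fill);
        out(i, j) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                    fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  return out;
}
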