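// Convolution kernels for the compact detection networks.
//
// Tensors cross the R/C++ boundary as numeric arrays of dim (H, W, C),
// which map directly onto arma::cube (rows, cols, slices). Convolution is
// im2col + GEMM; the column matrix is returned to R and passed back for the
// backward pass so it is built only once per forward.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Column layout: column index = oi + oj * Ho (output position, column-major);
// row index = di + dj * k + c * k * k (patch offset, then channel). Iteration
// is row-wise over (c, dj, di) with precomputed valid output ranges so the
// inner loops are tight strided copies.
static inline void valid_range(int d, int pad, int stride, int n, int n_out,
                               int& o_lo, int& o_hi) {
  // indices o with 0 <= o*stride + d - pad < n
  int lo = pad - d;
  o_lo = lo <= 0 ? 0 : (lo + stride - 1) / stride;
  int hi = n - 1 - d + pad;
  o_hi = hi < 0 ? -1 : hi / stride;
  if (o_hi > n_out - 1) o_hi = n_out - 1;
}

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(k * k * C, (size_t)Ho * Wo, arma::fill::zeros);
  const size_t nrow = (size_t)k * k * C;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      int oj_lo, oj_hi;
      valid_range(dj, pad, stride, W, Wo, oj_lo, oj_hi);
      for (int di = 0; di < k; ++di) {
        int oi_lo, oi_hi;
        valid_range(di, pad, stride, H, Ho, oi_lo, oi_hi);
        if (oi_hi < oi_lo || oj_hi < oj_lo) continue;
        const size_t row = di + dj * k + (size_t)c * k * k;
        for (int oj = oj_lo; oj <= oj_hi; ++oj) {
          const int j = oj * stride + dj - pad;
          const double* src = xc + (size_t)j * H + (oi_lo * stride + di - pad);
          double* dst = col.memptr() + row + ((size_t)oj * Ho + oi_lo) * nrow;
          if (stride == 1) {
            for (int oi = oi_lo; oi <= oi_hi; ++oi) {
              *dst = *src;
              dst += nrow;
              ++src;
            }
          } else {
            for (int oi = oi_lo; oi <= oi_hi; ++oi) {
              *dst = *src;
              dst += nrow;
              src += stride;
            }
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat& dcol, int H, int W, int C, int k,
                         int stride, int pad, int Ho, int Wo) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const size_t nrow = (size_t)k * k * C;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      int oj_lo, oj_hi;
      valid_range(dj, pad, stride, W, Wo, oj_lo, oj_hi);
      for (int di = 0; di < k; ++di) {
        int oi_lo, oi_hi;
        valid_range(di, pad, stride, H, Ho, oi_lo, oi_hi);
        if (oi_hi < oi_lo || oj_hi < oj_lo) continue;
        const size_t row = di + dj * k + (size_t)c * k * k;
        for (int oj = oj_lo; oj <= oj_hi; ++oj) {
          const int j = oj * stride + dj - pad;
          double* dst = dxc + (size_t)j * H + (oi_lo * stride + di - pad);
          const double* src = dcol.memptr() + row + ((size_t)oj * Ho + oi_lo) * nrow;
          for (int oi = oi_lo; oi <= oi_hi; ++oi) {
            *dst += *src;
            src += nrow;
            dst += stride;
          }
        }
      }
    }
  }
  return dx;
}

// Zero-copy view onto the R array's memory (read-only use).
static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2],
                    false, true);
}

static NumericVector cube_to_r(const arma::cube& x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, const arma::mat& w, const arma::vec& b,
                  int k, int stride, int pad, bool want_col) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat col = im2col(xc, k, stride, pad, Ho, Wo);
  arma::mat y = w.t() * col;  // Cout x (Ho*Wo)
  y.each_col() += b;
  arma::cube yc(Ho, Wo, w.n_cols);
  for (size_t c = 0; c < w.n_cols; ++c) {
    yc.slice(c) = arma::reshape(y.row(c), Ho, Wo);
  }
  List out = List::create(_["y"] = cube_to_r(yc));
  if (want_col) out["col"] = col;
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& col, const arma::mat& w, NumericVector dy,
                  IntegerVector xdim, int k, int stride, int pad,
                  bool want_dx) {
  arma::cube dyc = as_cube(dy);
  const int Ho = dyc.n_rows, Wo = dyc.n_cols, Cout = dyc.n_slices;
  arma::mat dymat(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    dymat.row(c) = arma::vectorise(dyc.slice(c)).t();
  }
  arma::mat dw = col * dymat.t();
  arma::vec db = arma::sum(dymat, 1);
  List out = List::create(_["dw"] = dw, _["db"] = db);
  if (want_dx) {
    arma::mat dcol = w * dymat;
    arma::cube dx = col2im(dcol, xdim[0], xdim[1], xdim[2], k, stride, pad,
                           Ho, Wo);
    out["dx"] = cube_to_r(dx);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube y(Ho, Wo, C);
  IntegerVector arg((size_t)Ho * Wo * C);
  size_t t = 0;
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -1e300;
        int besti = -1;
        const int i0 = oi * stride - pad, j0 = oj * stride - pad;
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= H) continue;
            const double v = xc(i, j, c);
            if (v > best) { best = v; besti = i + j * H + c * H * W; }
          }
        }
        y(oi, oj, c) = best;
        arg[t++] = besti;
      }
    }
  }
  // note: arg is filled in (oi fastest, then oj, then c)? No: loop order is
  // c outer, then oj, then oi -> linear index oi + oj*Ho + c*Ho*Wo matches t.
  return List::create(_["y"] = cube_to_r(y), _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector arg,
                              IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (R_xlen_t t = 0; t < dy.size(); ++t) {
    dx[arg[t]] += dy[t];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Fused channelwise LayerNorm + ReLU over an (H, W, C) tensor: normalizes
// across channels at each spatial position, applies gamma/beta, rectifies.
// [[Rcpp::export]]
List cpp_lnrelu_fwd(NumericVector x, const arma::vec& gamma,
                    const arma::vec& beta, bool relu) {
  IntegerVector dm = x.attr("dim");
  const int HW = dm[0] * dm[1], C = dm[2];
  NumericVector y((size_t)HW * C);
  NumericVector xn((size_t)HW * C);
  NumericVector istd(HW);
  LogicalVector mask(relu ? (size_t)HW * C : 0);
  const double eps = 1e-5;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* xnp = xn.begin();
  for (int p = 0; p < HW; ++p) {
    double mu = 0;
    for (int c = 0; c < C; ++c) mu += xp[p + (size_t)c * HW];
    mu /= C;
    double v = 0;
    for (int c = 0; c < C; ++c) {
      const double d = xp[p + (size_t)c * HW] - mu;
      v += d * d;
    }
    const double is = 1.0 / std::sqrt(v / C + eps);
    istd[p] = is;
    for (int c = 0; c < C; ++c) {
      const size_t idx = p + (size_t)c * HW;
      const double z = (xp[idx] - mu) * is;
      xnp[idx] = z;
      double out = z * gamma[c] + beta[c];
      if (relu) {
        const bool pos = out > 0;
        mask[idx] = pos;
        out = pos ? out : 0.0;
      }
      yp[idx] = out;
    }
  }
  y.attr("dim") = dm;
  List res = List::create(_["y"] = y, _["xn"] = xn, _["istd"] = istd);
  if (relu) res["mask"] = mask;
  return res;
}

// [[Rcpp::export]]
List cpp_lnrelu_bwd(NumericVector dy, NumericVector xn, NumericVector istd,
                    const arma::vec& gamma, Nullable<LogicalVector> mask_) {
  IntegerVector dm = dy.attr("dim");
  const int HW = dm[0] * dm[1], C = dm[2];
  NumericVector dx((size_t)HW * C);
  arma::vec dgamma(C, arma::fill::zeros);
  arma::vec dbeta(C, arma::fill::zeros);
  const double* dyp = dy.begin();
  const double* xnp = xn.begin();
  double* dxp = dx.begin();
  const int* maskp = mask_.isNotNull() ?
    LOGICAL(((LogicalVector)mask_.get())) : nullptr;
  std::vector<double> dxn(C);
  for (int p = 0; p < HW; ++p) {
    double m1 = 0, m2 = 0;
    for (int c = 0; c < C; ++c) {
      const size_t idx = p + (size_t)c * HW;
      double g = dyp[idx];
      if (maskp && !maskp[idx]) g = 0.0;
      dgamma[c] += g * xnp[idx];
      dbeta[c] += g;
      const double t = g * gamma[c];
      dxn[c] = t;
      m1 += t;
      m2 += t * xnp[idx];
    }
    m1 /= C;
    m2 /= C;
    const double is = istd[p];
    for (int c = 0; c < C; ++c) {
      const size_t idx = p + (size_t)c * HW;
      dxp[idx] = is * (dxn[c] - m1 - xnp[idx] * m2);
    }
  }
  dx.attr("dim") = dm;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Batch soft-edged ellipse compositing for the stylized renderer. Mutates
// the image (H, W, 3) in place; the caller owns the buffer.
// [[Rcpp::export]]
void cpp_draw_ellipses(NumericVector img, const arma::vec& cx,
                       const arma::vec& cy, const arma::vec& a,
                       const arma::vec& b, const arma::vec& angle,
                       const arma::mat& rgb, const arma::vec& alpha) {
  IntegerVector dm = img.attr("dim");
  const int H = dm[0], W = dm[1];
  double* px = img.begin();
  const size_t plane = (size_t)H * W;
  for (arma::uword e = 0; e < cx.n_elem; ++e) {
    const double amax = std::max(a[e], b[e]);
    const double rmax = amax + 1.5;
    const double ca = std::cos(angle[e]), sa = std::sin(angle[e]);
    const int r0 = std::max(0, (int)std::floor(cy[e] - rmax));
    const int r1 = std::min(H - 1, (int)std::ceil(cy[e] + rmax));
    const int c0 = std::max(0, (int)std::floor(cx[e] - rmax));
    const int c1 = std::min(W - 1, (int)std::ceil(cx[e] + rmax));
    const double soft = amax / 0.75;
    for (int cc = c0; cc <= c1; ++cc) {
      const double dx = cc - cx[e];
      for (int rr = r0; rr <= r1; ++rr) {
        const double dy = rr - cy[e];
        const double u = ca * dx + sa * dy;
        const double v = -sa * dx + ca * dy;
        const double d = std::sqrt((u / a[e]) * (u / a[e]) +
                                   (v / b[e]) * (v / b[e]));
        double w = (1.0 + 0.75 / amax - d) * soft;
        if (w <= 0) continue;
        if (w > 1) w = 1;
        w *= alpha[e];
        const size_t base = rr + (size_t)cc * H;
        for (int ch = 0; ch < 3; ++ch) {
          double& p = px[base + ch * plane];
          p = p * (1 - w) + rgb(e, ch) * w;
        }
      }
    }
  }
}

// ---- fused sequence of plain conv + channelwise LayerNorm + ReLU blocks ---
// The compact backbone is a straight chain of such blocks; running the whole
// chain per C++ call removes the per-layer R dispatch from the training hot
// path. params: list of per-block lists (w, b, gamma, beta, k, stride, pad).

static void lnrelu_inplace(NumericVector y, const arma::vec& gamma,
                           const arma::vec& beta, NumericVector& xn,
                           NumericVector& istd, LogicalVector& mask) {
  IntegerVector dm = y.attr("dim");
  const int HW = dm[0] * dm[1], C = dm[2];
  xn = NumericVector((size_t)HW * C);
  istd = NumericVector(HW);
  mask = LogicalVector((size_t)HW * C);
  double* yp = y.begin();
  double* xnp = xn.begin();
  const double eps = 1e-5;
  for (int p = 0; p < HW; ++p) {
    double mu = 0;
    for (int c = 0; c < C; ++c) mu += yp[p + (size_t)c * HW];
    mu /= C;
    double v = 0;
    for (int c = 0; c < C; ++c) {
      const double d = yp[p + (size_t)c * HW] - mu;
      v += d * d;
    }
    const double is = 1.0 / std::sqrt(v / C + eps);
    istd[p] = is;
    for (int c = 0; c < C; ++c) {
      const size_t idx = p + (size_t)c * HW;
      const double z = (yp[idx] - mu) * is;
      xnp[idx] = z;
      double out = z * gamma[c] + beta[c];
      const bool pos = out > 0;
      mask[idx] = pos;
      yp[idx] = pos ? out : 0.0;
    }
  }
}

// [[Rcpp::export]]
List cpp_plainseq_fwd(NumericVector x, List params, IntegerVector level_after,
                      bool want_cache) {
  const int nb = params.size();
  List levels(level_after.size());
  List caches(want_cache ? nb : 0);
  NumericVector cur = x;
  for (int b = 0; b < nb; ++b) {
    List p = params[b];
    arma::mat w = p["w"];
    arma::vec bias = p["b"];
    arma::vec gamma = p["gamma"];
    arma::vec beta = p["beta"];
    const int k = p["k"], stride = p["stride"], pad = p["pad"];
    arma::cube xc = as_cube(cur);
    const int H = xc.n_rows, W = xc.n_cols;
    const int Ho = (H + 2 * pad - k) / stride + 1;
    const int Wo = (W + 2 * pad - k) / stride + 1;
    arma::mat col = im2col(xc, k, stride, pad, Ho, Wo);
    arma::mat ymat = w.t() * col;
    ymat.each_col() += bias;
    NumericVector y((size_t)Ho * Wo * w.n_cols);
    // ymat is Cout x (Ho*Wo); R array wants position-major within channel
    double* yp = y.begin();
    for (size_t c = 0; c < w.n_cols; ++c) {
      const size_t off = c * (size_t)Ho * Wo;
      for (size_t q = 0; q < (size_t)Ho * Wo; ++q) yp[off + q] = ymat(c, q);
    }
    y.attr("dim") = IntegerVector::create(Ho, Wo, (int)w.n_cols);
    NumericVector xn, istd;
    LogicalVector mask;
    lnrelu_inplace(y, gamma, beta, xn, istd, mask);
    if (want_cache) {
      caches[b] = List::create(_["col"] = col, _["xn"] = xn, _["istd"] = istd,
                               _["mask"] = mask,
                               _["xdim"] = IntegerVector::create(H, W, (int)xc.n_slices));
    }
    cur = y;
    for (int li = 0; li < level_after.size(); ++li) {
      if (level_after[li] == b + 1) levels[li] = cur;
    }
  }
  List out = List::create(_["levels"] = levels);
  if (want_cache) out["caches"] = caches;
  return out;
}

// [[Rcpp::export]]
List cpp_plainseq_bwd(List params, List caches, List dlevels,
                      IntegerVector level_after) {
  const int nb = params.size();
  List grads(nb);
  NumericVector d;  // gradient flowing backward (dim attr set)
  bool have_d = false;
  for (int b = nb - 1; b >= 0; --b) {
    // add any level gradient entering after this block
    for (int li = 0; li < level_after.size(); ++li) {
      if (level_after[li] == b + 1 && !Rf_isNull(dlevels[li])) {
        NumericVector dl = dlevels[li];
        if (!have_d) {
          d = clone(dl);
          have_d = true;
        } else {
          for (R_xlen_t t = 0; t < d.size(); ++t) d[t] += dl[t];
        }
      }
    }
    if (!have_d) { grads[b] = R_NilValue; continue; }
    List p = params[b];
    List cc = caches[b];
    arma::mat w = p["w"];
    arma::vec gamma = p["gamma"];
    const int k = p["k"], stride = p["stride"], pad = p["pad"];
    NumericVector xn = cc["xn"];
    NumericVector istd = cc["istd"];
    LogicalVector mask = cc["mask"];
    IntegerVector xdim = cc["xdim"];
    arma::mat col = cc["col"];
    IntegerVector dm = d.attr("dim");
    const int HW = dm[0] * dm[1], C = dm[2];
    arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
    NumericVector dln((size_t)HW * C);
    const double* dp = d.begin();
    const double* xnp = xn.begin();
    const int* mp = LOGICAL(mask);
    double* dlnp = dln.begin();
    std::vector<double> dxn(C);
    for (int q = 0; q < HW; ++q) {
      double m1 = 0, m2 = 0;
      for (int c = 0; c < C; ++c) {
        const size_t idx = q + (size_t)c * HW;
        double g = mp[idx] ? dp[idx] : 0.0;
        dgamma[c] += g * xnp[idx];
        dbeta[c] += g;
        const double t = g * gamma[c];
        dxn[c] = t;
        m1 += t;
        m2 += t * xnp[idx];
      }
      m1 /= C;
      m2 /= C;
      const double is = istd[q];
      for (int c = 0; c < C; ++c) {
        const size_t idx = q + (size_t)c * HW;
        dlnp[idx] = is * (dxn[c] - m1 - xnp[idx] * m2);
      }
    }
    // conv backward
    arma::mat dymat(C, (size_t)HW);
    for (int c = 0; c < C; ++c) {
      for (int q = 0; q < HW; ++q) dymat(c, q) = dlnp[q + (size_t)c * HW];
    }
    arma::mat dw = col * dymat.t();
    arma::vec db = arma::sum(dymat, 1);
    grads[b] = List::create(_["dw"] = dw, _["db"] = db, _["dgamma"] = dgamma,
                            _["dbeta"] = dbeta);
    if (b > 0) {
      arma::mat dcol = w * dymat;
      arma::cube dx = col2im(dcol, xdim[0], xdim[1], xdim[2], k, stride, pad,
                             dm[0], dm[1]);
      d = cube_to_r(dx);
    }
  }
  return grads;
}

// Direct single-channel 2-D cross-correlation with zero padding (used by
// the matched-filter detector and the blur augmentation; no im2col buffer).
// [[Rcpp::export]]
NumericMatrix cpp_filter2d(NumericMatrix x, NumericMatrix kern) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = kern.nrow(), kw = kern.ncol();
  const int ph = kh / 2, pw = kw / 2;
  NumericMatrix y(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      const int di0 = std::max(0, ph - i), di1 = std::min(kh, H + ph - i);
      const int dj0 = std::max(0, pw - j), dj1 = std::min(kw, W + pw - j);
      for (int dj = dj0; dj < dj1; ++dj) {
        const int jj = j + dj - pw;
        for (int di = di0; di < di1; ++di) {
          acc += x(i + di - ph, jj) * kern(di, dj);
        }
      }
      y(i, j) = acc;
    }
  }
  return y;
}

// ---- fused feature pyramid + shared detection head ------------------------
// Runs lateral 1x1 convs, top-down factor-2 upsampling with addition, 3x3
// smoothing, the shared head tower (conv+ReLU) and the shared cls/ctr/reg
// convs for all three levels in one call each way. Weights of the shared
// head accumulate gradients across levels.

struct ConvP {
  arma::mat w;
  arma::vec b;
  int k, stride, pad;
};

static ConvP conv_from_list(List p) {
  ConvP c;
  c.w = as<arma::mat>(p["w"]);
  c.b = as<arma::vec>(p["b"]);
  c.k = p["k"];
  c.stride = p["stride"];
  c.pad = p["pad"];
  return c;
}

static NumericVector conv_raw_fwd(const NumericVector& x, const ConvP& cp,
                                  arma::mat* col_keep) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols;
  const int Ho = (H + 2 * cp.pad - cp.k) / cp.stride + 1;
  const int Wo = (W + 2 * cp.pad - cp.k) / cp.stride + 1;
  arma::mat col = im2col(xc, cp.k, cp.stride, cp.pad, Ho, Wo);
  arma::mat ymat = cp.w.t() * col;
  ymat.each_col() += cp.b;
  NumericVector y((size_t)Ho * Wo * cp.w.n_cols);
  double* yp = y.begin();
  for (size_t c = 0; c < cp.w.n_cols; ++c) {
    const size_t off = c * (size_t)Ho * Wo;
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q) yp[off + q] = ymat(c, q);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, (int)cp.w.n_cols);
  if (col_keep) *col_keep = std::move(col);
  return y;
}

// backward through a conv: returns dx, accumulates dw/db
static NumericVector conv_raw_bwd(const NumericVector& dy, const ConvP& cp,
                                  const arma::mat& col, IntegerVector xdim,
                                  arma::mat& dw_acc, arma::vec& db_acc,
                                  bool want_dx) {
  IntegerVector dm = dy.attr("dim");
  const int Ho = dm[0], Wo = dm[1], Cout = dm[2];
  arma::mat dymat(Cout, (size_t)Ho * Wo);
  const double* dp = dy.begin();
  for (int c = 0; c < Cout; ++c) {
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q) {
      dymat(c, q) = dp[q + (size_t)c * Ho * Wo];
    }
  }
  dw_acc += col * dymat.t();
  db_acc += arma::sum(dymat, 1);
  if (!want_dx) return NumericVector(0);
  arma::mat dcol = cp.w * dymat;
  arma::cube dx = col2im(dcol, xdim[0], xdim[1], xdim[2], cp.k, cp.stride,
                         cp.pad, Ho, Wo);
  return cube_to_r(dx);
}

static NumericVector up2_add(const NumericVector& coarse,
                             const NumericVector& fine) {
  IntegerVector dc = coarse.attr("dim");
  IntegerVector df = fine.attr("dim");
  NumericVector out = clone(fine);
  const int Hf = df[0], Wf = df[1], C = df[2];
  const int Hc = dc[0];
  const double* cp = coarse.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wf; ++j) {
      const size_t coff = (size_t)c * Hc * dc[1] + (size_t)(j / 2) * Hc;
      const size_t foff = (size_t)c * Hf * Wf + (size_t)j * Hf;
      for (int i = 0; i < Hf; ++i) {
        op[foff + i] += cp[coff + i / 2];
      }
    }
  }
  return out;
}

static NumericVector sumpool2(const NumericVector& dfine, IntegerVector dc) {
  IntegerVector df = dfine.attr("dim");
  NumericVector out((size_t)dc[0] * dc[1] * dc[2]);
  const int Hf = df[0], Wf = df[1], C = df[2];
  const int Hc = dc[0];
  const double* fp = dfine.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wf; ++j) {
      const size_t coff = (size_t)c * Hc * dc[1] + (size_t)(j / 2) * Hc;
      const size_t foff = (size_t)c * Hf * Wf + (size_t)j * Hf;
      for (int i = 0; i < Hf; ++i) {
        op[coff + i / 2] += fp[foff + i];
      }
    }
  }
  out.attr("dim") = dc;
  return out;
}

// [[Rcpp::export]]
List cpp_fpn_head_fwd(List levels, List lat, List smooth, List tower,
                      List cls, List ctr, List reg, bool want_cache) {
  std::vector<ConvP> latp, smoothp, towerp;
  for (int l = 0; l < 3; ++l) latp.push_back(conv_from_list(lat[l]));
  for (int l = 0; l < 3; ++l) smoothp.push_back(conv_from_list(smooth[l]));
  for (int t = 0; t < tower.size(); ++t) towerp.push_back(conv_from_list(tower[t]));
  ConvP clsp = conv_from_list(cls), ctrp = conv_from_list(ctr),
        regp = conv_from_list(reg);

  std::vector<arma::mat> lat_cols(3), smooth_cols(3);
  std::vector<std::vector<arma::mat>> tower_cols(3);
  std::vector<arma::mat> cls_cols(3), ctr_cols(3), reg_cols(3);
  List outs(3), cache_list;
  List lat_y(3), p_y(3), tower_masks(3), tower_ys(3), head_in(3);

  for (int l = 0; l < 3; ++l) {
    NumericVector lv = levels[l];
    lat_y[l] = conv_raw_fwd(lv, latp[l], want_cache ? &lat_cols[l] : nullptr);
  }
  // top-down
  p_y[2] = lat_y[2];
  p_y[1] = up2_add(p_y[2], lat_y[1]);
  p_y[0] = up2_add(p_y[1], lat_y[0]);

  for (int l = 0; l < 3; ++l) {
    NumericVector sm = conv_raw_fwd(p_y[l], smoothp[l],
                                    want_cache ? &smooth_cols[l] : nullptr);
    NumericVector h = sm;
    List masks(towerp.size());
    List hys(towerp.size());
    tower_cols[l].resize(towerp.size());
    for (size_t t = 0; t < towerp.size(); ++t) {
      NumericVector y = conv_raw_fwd(h, towerp[t],
                                     want_cache ? &tower_cols[l][t] : nullptr);
      LogicalVector mask(y.size());
      for (R_xlen_t q = 0; q < y.size(); ++q) {
        if (y[q] > 0) mask[q] = true; else y[q] = 0;
      }
      masks[t] = mask;
      hys[t] = y;
      h = y;
    }
    tower_masks[l] = masks;
    tower_ys[l] = hys;
    head_in[l] = h;
    NumericVector ocls = conv_raw_fwd(h, clsp, want_cache ? &cls_cols[l] : nullptr);
    NumericVector octr = conv_raw_fwd(h, ctrp, want_cache ? &ctr_cols[l] : nullptr);
    NumericVector oreg = conv_raw_fwd(h, regp, want_cache ? &reg_cols[l] : nullptr);
    outs[l] = List::create(_["cls"] = ocls, _["ctr"] = octr, _["reg"] = oreg);
  }
  List res = List::create(_["outs"] = outs);
  if (want_cache) {
    // store arma mats via XPtr-free route: wrap each into a list of matrices
    List lc(3), sc(3), cc(3), rc(3), kc(3), tc(3);
    for (int l = 0; l < 3; ++l) {
      lc[l] = lat_cols[l];
      sc[l] = smooth_cols[l];
      cc[l] = cls_cols[l];
      kc[l] = ctr_cols[l];
      rc[l] = reg_cols[l];
      List tcl(towerp.size());
      for (size_t t = 0; t < towerp.size(); ++t) tcl[t] = tower_cols[l][t];
      tc[l] = tcl;
    }
    res["cache"] = List::create(
      _["lat_cols"] = lc, _["smooth_cols"] = sc, _["tower_cols"] = tc,
      _["cls_cols"] = cc, _["ctr_cols"] = kc, _["reg_cols"] = rc,
      _["tower_masks"] = tower_masks, _["p_y"] = p_y, _["lat_y"] = lat_y,
      _["head_in"] = head_in, _["levels_dim"] = levels);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_fpn_head_bwd(List douts, List cache, List lat, List smooth,
                      List tower, List cls, List ctr, List reg) {
  std::vector<ConvP> latp, smoothp, towerp;
  for (int l = 0; l < 3; ++l) latp.push_back(conv_from_list(lat[l]));
  for (int l = 0; l < 3; ++l) smoothp.push_back(conv_from_list(smooth[l]));
  for (int t = 0; t < tower.size(); ++t) towerp.push_back(conv_from_list(tower[t]));
  ConvP clsp = conv_from_list(cls), ctrp = conv_from_list(ctr),
        regp = conv_from_list(reg);
  const int T = towerp.size();

  List lat_cols = cache["lat_cols"], smooth_cols = cache["smooth_cols"],
       tower_cols = cache["tower_cols"], cls_cols = cache["cls_cols"],
       ctr_cols = cache["ctr_cols"], reg_cols = cache["reg_cols"],
       tower_masks = cache["tower_masks"], p_y = cache["p_y"],
       lat_y = cache["lat_y"], head_in = cache["head_in"],
       levels_in = cache["levels_dim"];

  // gradient accumulators
  std::vector<arma::mat> dlat_w(3), dsmooth_w(3), dtower_w(T);
  std::vector<arma::vec> dlat_b(3), dsmooth_b(3), dtower_b(T);
  arma::mat dcls_w(clsp.w.n_rows, clsp.w.n_cols, arma::fill::zeros);
  arma::vec dcls_b(clsp.w.n_cols, arma::fill::zeros);
  arma::mat dctr_w(ctrp.w.n_rows, ctrp.w.n_cols, arma::fill::zeros);
  arma::vec dctr_b(ctrp.w.n_cols, arma::fill::zeros);
  arma::mat dreg_w(regp.w.n_rows, regp.w.n_cols, arma::fill::zeros);
  arma::vec dreg_b(regp.w.n_cols, arma::fill::zeros);
  for (int l = 0; l < 3; ++l) {
    dlat_w[l] = arma::mat(latp[l].w.n_rows, latp[l].w.n_cols, arma::fill::zeros);
    dlat_b[l] = arma::vec(latp[l].w.n_cols, arma::fill::zeros);
    dsmooth_w[l] = arma::mat(smoothp[l].w.n_rows, smoothp[l].w.n_cols, arma::fill::zeros);
    dsmooth_b[l] = arma::vec(smoothp[l].w.n_cols, arma::fill::zeros);
  }
  for (int t = 0; t < T; ++t) {
    dtower_w[t] = arma::mat(towerp[t].w.n_rows, towerp[t].w.n_cols, arma::fill::zeros);
    dtower_b[t] = arma::vec(towerp[t].w.n_cols, arma::fill::zeros);
  }

  List dp(3);
  for (int l = 0; l < 3; ++l) {
    List dl = douts[l];
    NumericVector hin = head_in[l];
    IntegerVector hdim = hin.attr("dim");
    NumericVector dh = conv_raw_bwd(dl["dcls"], clsp, cls_cols[l], hdim,
                                    dcls_w, dcls_b, true);
    NumericVector dh2 = conv_raw_bwd(dl["dctr"], ctrp, ctr_cols[l], hdim,
                                     dctr_w, dctr_b, true);
    NumericVector dh3 = conv_raw_bwd(dl["dreg"], regp, reg_cols[l], hdim,
                                     dreg_w, dreg_b, true);
    for (R_xlen_t q = 0; q < dh.size(); ++q) dh[q] += dh2[q] + dh3[q];
    // tower backward
    List masks = tower_masks[l];
    List tcl = tower_cols[l];
    for (int t = T - 1; t >= 0; --t) {
      LogicalVector mask = masks[t];
      for (R_xlen_t q = 0; q < dh.size(); ++q) {
        if (!mask[q]) dh[q] = 0;
      }
      // all tower convs are C -> C at stride 1: input dims equal head dims
      IntegerVector xd = hdim;
      dh = conv_raw_bwd(dh, towerp[t], tcl[t], xd, dtower_w[t], dtower_b[t],
                        true);
    }
    // smoothing conv backward: input p_y[l]
    NumericVector pin = p_y[l];
    IntegerVector pdim = pin.attr("dim");
    dp[l] = conv_raw_bwd(dh, smoothp[l], smooth_cols[l], pdim,
                         dsmooth_w[l], dsmooth_b[l], true);
  }
  // top-down backward: p0 = lat0 + up2(p1); p1 = lat1 + up2(p2); p2 = lat2
  NumericVector dp0 = dp[0], dp1 = dp[1], dp2 = dp[2];
  NumericVector dlat0 = dp0;
  NumericVector up1 = ((NumericVector)lat_y[1]);
  IntegerVector d1 = up1.attr("dim");
  NumericVector add1 = sumpool2(dp0, d1);
  for (R_xlen_t q = 0; q < dp1.size(); ++q) dp1[q] += add1[q];
  NumericVector dlat1 = dp1;
  NumericVector up2v = ((NumericVector)lat_y[2]);
  IntegerVector d2 = up2v.attr("dim");
  NumericVector add2 = sumpool2(dp1, d2);
  for (R_xlen_t q = 0; q < dp2.size(); ++q) dp2[q] += add2[q];
  NumericVector dlat2 = dp2;

  List dlevels(3);
  NumericVector dls[3] = {dlat0, dlat1, dlat2};
  for (int l = 0; l < 3; ++l) {
    NumericVector lv = levels_in[l];
    IntegerVector ldim = lv.attr("dim");
    dlevels[l] = conv_raw_bwd(dls[l], latp[l], lat_cols[l], ldim,
                              dlat_w[l], dlat_b[l], true);
  }

  List gl(3), gs(3), gt(T);
  for (int l = 0; l < 3; ++l) {
    gl[l] = List::create(_["dw"] = dlat_w[l], _["db"] = dlat_b[l]);
    gs[l] = List::create(_["dw"] = dsmooth_w[l], _["db"] = dsmooth_b[l]);
  }
  for (int t = 0; t < T; ++t) {
    gt[t] = List::create(_["dw"] = dtower_w[t], _["db"] = dtower_b[t]);
  }
  return List::create(
    _["dlevels"] = dlevels, _["lat"] = gl, _["smooth"] = gs, _["tower"] = gt,
    _["cls"] = List::create(_["dw"] = dcls_w, _["db"] = dcls_b),
    _["ctr"] = List::create(_["dw"] = dctr_w, _["db"] = dctr_b),
    _["reg"] = List::create(_["dw"] = dreg_w, _["db"] = dreg_b));
}
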