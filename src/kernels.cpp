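// Low-level numerical kernels: 2D image primitives (median filter, bilinear /
// nearest resampling, rigid rotation), 3D connected-component labeling by
// breadth-first search, and the convolution / pooling operators used by the
// residual attention network. Tensors follow R's column-major layout with
// dimensions [H, W, C, N]; convolution kernels are [kh, kw, C, F].
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // simple reflection: index −1 maps back to 0 (the border sample repeats),
  // unlike reflect-101 which would map −1 to 1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter2d(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel side must be an odd integer >= 1");
  int H = x.nrow(), W = x.ncol(), r = k / 2, m = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(m);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int t = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = reflect_idx(j + dj, W);
        for (int di = -r; di <= r; ++di)
          buf[t++] = x(reflect_idx(i + di, H), cj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Pixel-center coordinate mapping: source = (dst + 0.5) * (in/out) - 0.5.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int oh, int ow) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(oh, ow);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      out(i, j) = (1 - wy) * ((1 - wx) * x(y0c, x0c) + wx * x(y0c, x1c)) +
                  wy * ((1 - wx) * x(y1c, x0c) + wx * x(y1c, x1c));
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(IntegerMatrix x, int oh, int ow) {
  int H = x.nrow(), W = x.ncol();
  IntegerMatrix out(oh, ow);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    int sj = std::min((int)std::floor((j + 0.5) * sx), W - 1);
    for (int i = 0; i < oh; ++i) {
      int si = std::min((int)std::floor((i + 0.5) * sy), H - 1);
      out(i, j) = x(si, sj);
    }
  }
  return out;
}

// Rigid rotation about the image center (degrees, counter-clockwise in the
// row/col plane), optional horizontal flip applied first, zero fill outside.
// nearest = true switches to nearest-neighbour sampling (for label grids).
// [[Rcpp::export]]
NumericMatrix cpp_warp_rotate(NumericMatrix x, double angle_deg, bool flip,
                              bool nearest) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  double th = angle_deg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // inverse map: rotate destination offset by -angle
      double dy = i - cy, dx = j - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      if (flip) sx = (W - 1) - sx;
      if (nearest) {
        int si = (int)std::lround(sy), sj = (int)std::lround(sx);
        out(i, j) = (si >= 0 && si < H && sj >= 0 && sj < W) ? x(si, sj) : 0.0;
      } else {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double wy = sy - y0, wx = sx - x0;
        double acc = 0.0;
        for (int b = 0; b <= 1; ++b) {
          int yy = y0 + b;
          if (yy < 0 || yy >= H) continue;
          for (int a = 0; a <= 1; ++a) {
            int xx = x0 + a;
            if (xx < 0 || xx >= W) continue;
            acc += (b ? wy : 1 - wy) * (a ? wx : 1 - wx) * x(yy, xx);
          }
        }
        out(i, j) = acc;
      }
    }
  }
  return out;
}

// 3D connected components over voxels equal to `target`, BFS traversal.
// labels assigned first_id, first_id+1, ... in scan order (slice, row, col)
// of the seed voxel. dims are (S, H, W); conn in {6, 18, 26}.
// [[Rcpp::export]]
IntegerVector cpp_label_components3d(IntegerVector mask, IntegerVector dims,
                                     int target, int conn, int first_id) {
  int S = dims[0], H = dims[1], W = dims[2];
  if (conn != 6 && conn != 18 && conn != 26) stop("connectivity must be 6, 18 or 26");
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dims;
  // neighbour offsets
  std::vector<std::array<int, 3>> nb;
  for (int ds = -1; ds <= 1; ++ds)
    for (int dh = -1; dh <= 1; ++dh)
      for (int dw = -1; dw <= 1; ++dw) {
        int nz = std::abs(ds) + std::abs(dh) + std::abs(dw);
        if (nz == 0) continue;
        if (conn == 6 && nz > 1) continue;
        if (conn == 18 && nz > 2) continue;
        nb.push_back({ds, dh, dw});
      }
  int next_id = first_id;
  auto IDX = [&](int s, int h, int w) { return s + S * (h + (long long)H * w); };
  // seed scan in lexicographic (slice, row, col) order
  for (int s = 0; s < S; ++s)
    for (int h = 0; h < H; ++h)
      for (int w = 0; w < W; ++w) {
        long long i0 = IDX(s, h, w);
        if (mask[i0] != target || lab[i0] != 0) continue;
        std::queue<std::array<int, 3>> q;
        q.push({s, h, w});
        lab[i0] = next_id;
        while (!q.empty()) {
          auto v = q.front();
          q.pop();
          for (auto &d : nb) {
            int ns = v[0] + d[0], nh = v[1] + d[1], nw = v[2] + d[2];
            if (ns < 0 || ns >= S || nh < 0 || nh >= H || nw < 0 || nw >= W)
              continue;
            long long ni = IDX(ns, nh, nw);
            if (mask[ni] == target && lab[ni] == 0) {
              lab[ni] = next_id;
              q.push({ns, nh, nw});
            }
          }
        }
        ++next_id;
      }
  return lab;
}

// ---------------- convolution / pooling ----------------

static arma::mat im2col(const double *x, int H, int W, int C, int kh, int kw,
                        int stride, int pad, int OH, int OW) {
  arma::mat col(kh * kw * C, (long long)OH * OW);
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (long long)H * W * c;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * stride - pad + kj;
          double *dst = col.memptr() + row + (long long)col.n_rows * OH * ow;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[(long long)col.n_rows * oh] = 0.0;
            continue;
          }
          const double *src = xc + (long long)H * wi;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * stride - pad + ki;
            dst[(long long)col.n_rows * oh] =
                (hi >= 0 && hi < H) ? src[hi] : 0.0;
          }
        }
      }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("channel mismatch in convolution");
  int OH = (H + 2 * pad - kh) / stride + 1, OW = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  NumericVector out((long long)OH * OW * F * N);
  out.attr("dim") = IntegerVector::create(OH, OW, F, N);
  arma::vec b;
  if (bias.isNotNull()) b = as<arma::vec>(bias.get());
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (long long)H * W * C * n, H, W, C, kh,
                           kw, stride, pad, OH, OW);
    arma::mat Yt = col.t() * Wm;  // (OH*OW) x F
    if (b.n_elem) Yt.each_row() += b.t();
    std::copy(Yt.begin(), Yt.end(), out.begin() + (long long)OH * OW * F * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int OH = yd[0], OW = yd[1];
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  NumericVector dx((long long)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dW(kh * kw * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (long long)H * W * C * n, H, W, C, kh,
                           kw, stride, pad, OH, OW);
    arma::mat dYt(const_cast<double *>(dy.begin()) + (long long)OH * OW * F * n,
                  (long long)OH * OW, F, false, true);
    dW += col * dYt;
    db += arma::sum(dYt, 0).t();
    arma::mat dcol = Wm * dYt.t();  // K x P
    // col2im scatter-add
    double *dxn = dx.begin() + (long long)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki) {
          int row = ki + kh * (kj + kw * c);
          for (int ow = 0; ow < OW; ++ow) {
            int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dxn[hi + (long long)H * wi + (long long)H * W * c] +=
                  dcol(row, oh + (long long)OH * ow);
            }
          }
        }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = (H + 2 * pad - k) / stride + 1, OW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((long long)OH * OW * C * N);
  IntegerVector arg(out.size());  // flat (h + H*w) index within the channel
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  arg.attr("dim") = out.attr("dim");
  long long p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (long long)H * W * (c + (long long)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = ow * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = oh * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (long long)H * wi];
              if (v > best) { best = v; bidx = hi + H * wi; }
            }
          }
          long long q = oh + (long long)OH * (ow + (long long)OW * (c + (long long)C * n));
          out[q] = best;
          arg[q] = bidx;
          ++p;
        }
    }
  (void)p;
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector arg,
                              IntegerVector in_dim) {
  IntegerVector yd = dy.attr("dim");
  int OH = yd[0], OW = yd[1], C = yd[2], N = yd[3];
  int H = in_dim[0], W = in_dim[1];
  NumericVector dx((long long)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dxc = dx.begin() + (long long)H * W * (c + (long long)C * n);
      long long base = (long long)OH * OW * (c + (long long)C * n);
      for (long long q = 0; q < (long long)OH * OW; ++q)
        dxc[arg[base + q]] += dy[base + q];
    }
  return dx;
}

// ---------------- fused batch-norm / relu / pooling helpers ----------------

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, double eps,
                double momentum, bool train) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  long long HW = (long long)H * W, m = HW * N;
  NumericVector mu(C), va(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double *p = x.begin() + HW * (c + (long long)C * n);
        for (long long i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[c] = s / m;
      va[c] = s2 / m - mu[c] * mu[c];
    }
  } else {
    mu = rmean; va = rvar;
  }
  NumericVector y(x.size()), xhat(train ? x.size() : 0);
  y.attr("dim") = d;
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(va[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (long long)C * n);
      double *py = y.begin() + HW * (c + (long long)C * n);
      double g = gamma[c], b = beta[c], mc = mu[c], is = istd[c];
      if (train) {
        double *ph = xhat.begin() + HW * (c + (long long)C * n);
        for (long long i = 0; i < HW; ++i) {
          ph[i] = (p[i] - mc) * is;
          py[i] = g * ph[i] + b;
        }
      } else {
        for (long long i = 0; i < HW; ++i) py[i] = g * (p[i] - mc) * is + b;
      }
    }
  NumericVector nrm(C), nrv(C);
  if (train) {
    xhat.attr("dim") = d;
    for (int c = 0; c < C; ++c) {
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      nrv[c] = (1 - momentum) * rvar[c] + momentum * va[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector istd,
                NumericVector gamma) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  long long HW = (long long)H * W, m = HW * N;
  NumericVector dgamma(C), dbeta(C), dx(dy.size());
  dx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double *pd = dy.begin() + HW * (c + (long long)C * n);
      const double *ph = xhat.begin() + HW * (c + (long long)C * n);
      for (long long i = 0; i < HW; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    double g = gamma[c] * istd[c], mg = sg / m, mb = sb / m;
    for (int n = 0; n < N; ++n) {
      const double *pd = dy.begin() + HW * (c + (long long)C * n);
      const double *ph = xhat.begin() + HW * (c + (long long)C * n);
      double *px = dx.begin() + HW * (c + (long long)C * n);
      for (long long i = 0; i < HW; ++i)
        px[i] = g * (pd[i] - mb - ph[i] * mg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (double &v : y) if (v < 0) v = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// per-channel average and max (with argmax) over the spatial extent
// [[Rcpp::export]]
List cpp_pool_hw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  long long HW = (long long)H * W;
  NumericMatrix avg(C, N), mx(C, N);
  IntegerMatrix arg(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (long long)C * n);
      double s = 0, best = p[0];
      int bi = 0;
      for (long long i = 0; i < HW; ++i) {
        s += p[i];
        if (p[i] > best) { best = p[i]; bi = (int)i; }
      }
      avg(c, n) = s / HW;
      mx(c, n) = best;
      arg(c, n) = bi + 1;  // 1-based within the channel plane
    }
  return List::create(_["avg"] = avg, _["max"] = mx, _["arg"] = arg);
}

// per-position mean and max (with arg channel) over channels
// [[Rcpp::export]]
List cpp_pool_c(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  long long HW = (long long)H * W;
  NumericVector spin((long long)H * W * 2 * N);
  spin.attr("dim") = IntegerVector::create(H, W, 2, N);
  IntegerVector arg((long long)H * W * N);
  arg.attr("dim") = IntegerVector::create(H, W, N);
  for (int n = 0; n < N; ++n) {
    double *pm = spin.begin() + (long long)2 * HW * n;
    double *px = pm + HW;
    int *pa = arg.begin() + HW * n;
    const double *x0 = x.begin() + HW * (long long)C * n;
    for (long long i = 0; i < HW; ++i) {
      double s = 0, best = x0[i];
      int bc = 0;
      for (int c = 0; c < C; ++c) {
        double v = x0[i + HW * c];
        s += v;
        if (v > best) { best = v; bc = c; }
      }
      pm[i] = s / C;
      px[i] = best;
      pa[i] = bc + 1;
    }
  }
  return List::create(_["spin"] = spin, _["arg"] = arg);
}

// x[H,W,C,N] * w[C,N], broadcast over positions
// [[Rcpp::export]]
NumericVector cpp_scale_channels(NumericVector x, NumericMatrix w) {
  IntegerVector d = x.attr("dim");
  int C = d[2], N = d[3];
  long long HW = (long long)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (long long)C * n);
      double *py = y.begin() + HW * (c + (long long)C * n);
      double wc = w(c, n);
      for (long long i = 0; i < HW; ++i) py[i] = p[i] * wc;
    }
  return y;
}

// x[H,W,C,N] * m[H,W,N], broadcast over channels
// [[Rcpp::export]]
NumericVector cpp_scale_spatial(NumericVector x, NumericVector m) {
  IntegerVector d = x.attr("dim");
  int C = d[2], N = d[3];
  long long HW = (long long)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double *pm = m.begin() + HW * n;
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (long long)C * n);
      double *py = y.begin() + HW * (c + (long long)C * n);
      for (long long i = 0; i < HW; ++i) py[i] = p[i] * pm[i];
    }
  }
  return y;
}

// per-sample, per-position sum over channels of a*b (spatial-attention grad)
// [[Rcpp::export]]
NumericVector cpp_sum_channels_prod(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  int C = d[2], N = d[3];
  long long HW = (long long)d[0] * d[1];
  NumericVector out(HW * (long long)N);
  out.attr("dim") = IntegerVector::create(d[0], d[1], N);
  for (int n = 0; n < N; ++n) {
    double *po = out.begin() + HW * n;
    for (int c = 0; c < C; ++c) {
      const double *pa = a.begin() + HW * (c + (long long)C * n);
      const double *pb = b.begin() + HW * (c + (long long)C * n);
      for (long long i = 0; i < HW; ++i) po[i] += pa[i] * pb[i];
    }
  }
  return out;
}

// per-channel sum over positions of a*b (channel-attention grad), C x N
// [[Rcpp::export]]
NumericMatrix cpp_sum_hw_prod(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  int C = d[2], N = d[3];
  long long HW = (long long)d[0] * d[1];
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *pa = a.begin() + HW * (c + (long long)C * n);
      const double *pb = b.begin() + HW * (c + (long long)C * n);
      double s = 0;
      for (long long i = 0; i < HW; ++i) s += pa[i] * pb[i];
      out(c, n) = s;
    }
  return out;
}
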