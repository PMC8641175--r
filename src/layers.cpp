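// Hot numerical kernels of the window-classifier encoder.
//
// Activations are (h*w*N) x C matrices; row r addresses spatial position
// (i, j) of window n with r = i + j*h + n*h*w (0-based). Convolution is
// 3x3, stride 1, zero ('same') padding, computed as one GEMM against an
// im2col matrix whose column block o = 3*(dj+1) + (di+1) holds the input
// shifted by (di, dj). Keeping the im2col buffers and pooling temporaries
// in C++ avoids churning R's garbage collector with multi-megabyte
// intermediates on every training step.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col3(const arma::mat& x, int h, int w, int N) {
  const int cin = x.n_cols, hw = h * w;
  arma::mat X(static_cast<arma::uword>(hw) * N, 9 * cin);
  for (int o = 0; o < 9; ++o) {
    const int di = o % 3 - 1, dj = o / 3 - 1;
    for (int c = 0; c < cin; ++c) {
      double* dst = X.colptr(o * cin + c);
      const double* src = x.colptr(c);
      for (int n = 0; n < N; ++n) {
        for (int j = 0; j < w; ++j) {
          double* d = dst + static_cast<size_t>(n) * hw + static_cast<size_t>(j) * h;
          const int js = j + dj;
          if (js < 0 || js >= w) { std::fill(d, d + h, 0.0); continue; }
          const double* s = src + static_cast<size_t>(n) * hw + static_cast<size_t>(js) * h;
          const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
          if (i0 > 0) std::fill(d, d + i0, 0.0);
          std::copy(s + i0 + di, s + i1 + di, d + i0);
          if (i1 < h) std::fill(d + i1, d + h, 0.0);
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const arma::mat& x, int h, int w, int N,
                        const arma::mat& W, const arma::vec& b) {
  arma::mat y = im2col3(x, h, w, N) * W;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const arma::mat& x, const arma::mat& dY, int h, int w,
                   int N, const arma::mat& W) {
  const int cin = x.n_cols, hw = h * w;
  arma::mat X = im2col3(x, h, w, N);
  arma::mat dW = X.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dXcol = dY * W.t();
  arma::mat dx(x.n_rows, cin, arma::fill::zeros);
  for (int o = 0; o < 9; ++o) {
    const int di = o % 3 - 1, dj = o / 3 - 1;
    for (int c = 0; c < cin; ++c) {
      const double* src = dXcol.colptr(o * cin + c);
      double* dst = dx.colptr(c);
      for (int n = 0; n < N; ++n) {
        for (int j = 0; j < w; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= w) continue;
          const double* s = src + static_cast<size_t>(n) * hw + static_cast<size_t>(j) * h;
          double* d = dst + static_cast<size_t>(n) * hw + static_cast<size_t>(js) * h;
          const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
          for (int i = i0; i < i1; ++i) d[i + di] += s[i];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Per-window channel sums: rows grouped in runs of hw -> N x C.
// [[Rcpp::export]]
arma::mat group_sums_cpp(const arma::mat& x, int hw) {
  const int N = x.n_rows / hw, C = x.n_cols;
  arma::mat out(N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      const double* s = src + static_cast<size_t>(n) * hw;
      for (int r = 0; r < hw; ++r) acc += s[r];
      out(n, c) = acc;
    }
  }
  return out;
}

// Segment sums of an elementwise product, without materialising it.
// [[Rcpp::export]]
arma::mat group_sums_prod_cpp(const arma::mat& x, const arma::mat& y,
                              int hw) {
  const int N = x.n_rows / hw, C = x.n_cols;
  arma::mat out(N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* a = x.colptr(c);
    const double* b = y.colptr(c);
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      const size_t o = static_cast<size_t>(n) * hw;
      for (int r = 0; r < hw; ++r) acc += a[o + r] * b[o + r];
      out(n, c) = acc;
    }
  }
  return out;
}

// y[r, c] = x[r, c] * s[g(r), c]  (channel re-weighting per window)
// [[Rcpp::export]]
arma::mat group_scale_cpp(const arma::mat& x, const arma::mat& s, int hw) {
  const int N = x.n_rows / hw, C = x.n_cols;
  arma::mat out(x.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double f = s(n, c);
      const size_t o = static_cast<size_t>(n) * hw;
      for (int r = 0; r < hw; ++r) dst[o + r] = src[o + r] * f;
    }
  }
  return out;
}

// y[r, c] = x[r, c] * s[g(r), c] + t[g(r), c]
// [[Rcpp::export]]
arma::mat group_scale_affine_cpp(const arma::mat& x, const arma::mat& s,
                                 const arma::mat& t, int hw) {
  const int N = x.n_rows / hw, C = x.n_cols;
  arma::mat out(x.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double f = s(n, c), a = t(n, c);
      const size_t o = static_cast<size_t>(n) * hw;
      for (int r = 0; r < hw; ++r) dst[o + r] = src[o + r] * f + a;
    }
  }
  return out;
}

// y[r, c] = s[g(r), c]
// [[Rcpp::export]]
arma::mat group_expand_cpp(const arma::mat& s, int hw) {
  const int N = s.n_rows, C = s.n_cols;
  arma::mat out(static_cast<arma::uword>(N) * hw, C);
  for (int c = 0; c < C; ++c) {
    double* dst = out.colptr(c);
    for (int n = 0; n < N; ++n)
      std::fill(dst + static_cast<size_t>(n) * hw,
                dst + static_cast<size_t>(n + 1) * hw, s(n, c));
  }
  return out;
}

// Max pooling with ph x pw windows (floor division of the spatial grid).
// Returns the pooled activations and the flat argmax candidate index.
// [[Rcpp::export]]
List maxpool_fwd_cpp(const arma::mat& x, int h, int w, int N, int ph,
                     int pw) {
  const int h2 = h / ph, w2 = w / pw, C = x.n_cols;
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hw2 = static_cast<size_t>(h2) * w2;
  arma::mat y(hw2 * N, C);
  IntegerMatrix which(hw2 * N, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int j2 = 0; j2 < w2; ++j2) {
        for (int i2 = 0; i2 < h2; ++i2) {
          double best = -std::numeric_limits<double>::infinity();
          int bk = 0;
          for (int dj = 0; dj < pw; ++dj) {
            for (int di = 0; di < ph; ++di) {
              const size_t r = n * hw +
                static_cast<size_t>(j2 * pw + dj) * h + (i2 * ph + di);
              if (src[r] > best) { best = src[r]; bk = dj * ph + di; }
            }
          }
          const size_t r2 = n * hw2 + static_cast<size_t>(j2) * h2 + i2;
          dst[r2] = best;
          which(r2, c) = bk;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["which_k"] = which);
}

// [[Rcpp::export]]
arma::mat maxpool_bwd_cpp(const arma::mat& dY, const IntegerMatrix& which,
                          int h, int w, int N, int ph, int pw) {
  const int h2 = h / ph, w2 = w / pw, C = dY.n_cols;
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hw2 = static_cast<size_t>(h2) * w2;
  arma::mat dx(hw * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = dY.colptr(c);
    double* dst = dx.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int j2 = 0; j2 < w2; ++j2) {
        for (int i2 = 0; i2 < h2; ++i2) {
          const size_t r2 = n * hw2 + static_cast<size_t>(j2) * h2 + i2;
          const int bk = which(r2, c);
          const int di = bk % ph, dj = bk / ph;
          const size_t r = n * hw +
            static_cast<size_t>(j2 * pw + dj) * h + (i2 * ph + di);
          dst[r] += src[r2];
        }
      }
    }
  }
  return dx;
}

// ---- full encoder ---------------------------------------------------------
//
// The six-block encoder runs entirely in C++: inter-layer activations and
// the caches needed for backpropagation stay in native memory (exposed to R
// only as an external pointer), so a training step performs no large R
// allocations. Parameters cross the boundary per call; they are small.

struct EncCache {
  int N = 0;
  std::vector<arma::mat> xcol;     // im2col inputs, reused for dW/dx
  std::vector<arma::mat> a;        // post-ReLU activations (SE inputs)
  std::vector<arma::mat> s, a1, gate;  // SE internals
  std::vector<arma::Mat<int>> which;   // max-pool argmax
};

static arma::mat avgpool_1x2_cpp(const NumericVector& X3, int n, int m,
                                 int N) {
  const int w = m / 2, hw = n * w;
  arma::mat out(static_cast<arma::uword>(hw) * N, 1);
  const double* src = X3.begin();
  double* dst = out.colptr(0);
  for (int nn = 0; nn < N; ++nn)
    for (int j = 0; j < w; ++j) {
      const double* s1 = src + static_cast<size_t>(nn) * n * m +
        static_cast<size_t>(2 * j) * n;
      const double* s2 = s1 + n;
      double* d = dst + static_cast<size_t>(nn) * hw +
        static_cast<size_t>(j) * n;
      for (int i = 0; i < n; ++i) d[i] = 0.5 * (s1[i] + s2[i]);
    }
  return out;
}

static void maxpool_block(const arma::mat& x, int h, int w, int N, int ph,
                          int pw, arma::mat& y, arma::Mat<int>& which,
                          bool keep_which) {
  const int h2 = h / ph, w2 = w / pw, C = x.n_cols;
  const size_t hw = static_cast<size_t>(h) * w;
  const size_t hw2 = static_cast<size_t>(h2) * w2;
  y.set_size(hw2 * N, C);
  if (keep_which) which.set_size(hw2 * N, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int j2 = 0; j2 < w2; ++j2)
        for (int i2 = 0; i2 < h2; ++i2) {
          double best = -std::numeric_limits<double>::infinity();
          int bk = 0;
          for (int dj = 0; dj < pw; ++dj)
            for (int di = 0; di < ph; ++di) {
              const size_t r = n * hw +
                static_cast<size_t>(j2 * pw + dj) * h + (i2 * ph + di);
              if (src[r] > best) { best = src[r]; bk = dj * ph + di; }
            }
          const size_t r2 = n * hw2 + static_cast<size_t>(j2) * h2 + i2;
          dst[r2] = best;
          if (keep_which) which(r2, c) = bk;
        }
  }
}

// params: flat list, 6 entries per block: W, b, W1, b1, W2, b2.
// trace: 6 x 6 integer matrix, rows (h, w, ph, pw, h2, w2).
// [[Rcpp::export]]
List encoder_fwd_cpp(const NumericVector& X3, int n, int m, int N,
                     const List& params, const IntegerMatrix& trace,
                     bool keep_cache) {
  EncCache* cache = new EncCache();
  cache->N = N;
  arma::mat x = avgpool_1x2_cpp(X3, n, m, N);
  for (int k = 0; k < 6; ++k) {
    const int h = trace(k, 0), w = trace(k, 1), ph = trace(k, 2),
      pw = trace(k, 3);
    const int hw = h * w;
    const arma::mat W = as<arma::mat>(params[6 * k]);
    const arma::vec b = as<arma::vec>(params[6 * k + 1]);
    const arma::mat W1 = as<arma::mat>(params[6 * k + 2]);
    const arma::vec b1 = as<arma::vec>(params[6 * k + 3]);
    const arma::mat W2 = as<arma::mat>(params[6 * k + 4]);
    const arma::vec b2 = as<arma::vec>(params[6 * k + 5]);
    arma::mat Xcol = im2col3(x, h, w, N);
    arma::mat a = Xcol * W;
    if (keep_cache) cache->xcol.push_back(std::move(Xcol));
    a.each_row() += b.t();
    a.transform([](double v) { return v > 0 ? v : 0.0; });   // ReLU
    arma::mat s = group_sums_cpp(a, hw) / hw;
    arma::mat a1 = s * W1;
    a1.each_row() += b1.t();
    a1.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat gate = a1 * W2;
    gate.each_row() += b2.t();
    gate.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    arma::mat scaled = group_scale_cpp(a, gate, hw);
    arma::mat pooled;
    arma::Mat<int> which;
    maxpool_block(scaled, h, w, N, ph, pw, pooled, which, keep_cache);
    if (keep_cache) {
      cache->a.push_back(std::move(a));
      cache->s.push_back(std::move(s));
      cache->a1.push_back(std::move(a1));
      cache->gate.push_back(std::move(gate));
      cache->which.push_back(std::move(which));
    }
    x = std::move(pooled);
  }
  const int h2 = trace(5, 4), w2 = trace(5, 5);
  arma::mat E = group_sums_cpp(x, h2 * w2) / (h2 * w2);
  XPtr<EncCache> ptr(cache, true);
  return List::create(_["E"] = E, _["cache"] = ptr);
}

// [[Rcpp::export]]
List encoder_bwd_cpp(SEXP cache_xp, const arma::mat& dE, const List& params,
                     const IntegerMatrix& trace) {
  XPtr<EncCache> cache(cache_xp);
  const int N = cache->N;
  List grads(36);
  const int h6 = trace(5, 4), w6 = trace(5, 5);
  arma::mat dx = group_expand_cpp(dE / (h6 * w6), h6 * w6);
  for (int k = 5; k >= 0; --k) {
    const int h = trace(k, 0), w = trace(k, 1), ph = trace(k, 2),
      pw = trace(k, 3), h2 = trace(k, 4), w2 = trace(k, 5);
    const int hw = h * w;
    const arma::mat W = as<arma::mat>(params[6 * k]);
    const arma::mat W1 = as<arma::mat>(params[6 * k + 2]);
    const arma::mat W2 = as<arma::mat>(params[6 * k + 4]);
    const arma::mat& a = cache->a[k];
    const arma::mat& gate = cache->gate[k];
    // max-pool backward
    const arma::Mat<int>& which = cache->which[k];
    const int C = dx.n_cols;
    const size_t hwN = static_cast<size_t>(hw) * N;
    const size_t hw2 = static_cast<size_t>(h2) * w2;
    arma::mat dse(hwN, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* src = dx.colptr(c);
      double* dst = dse.colptr(c);
      for (int nn = 0; nn < N; ++nn)
        for (int j2 = 0; j2 < w2; ++j2)
          for (int i2 = 0; i2 < h2; ++i2) {
            const size_t r2 = nn * hw2 + static_cast<size_t>(j2) * h2 + i2;
            const int bk = which(r2, c);
            const int di = bk % ph, dj = bk / ph;
            dst[nn * static_cast<size_t>(hw) +
                static_cast<size_t>(j2 * pw + dj) * h + (i2 * ph + di)] +=
              src[r2];
          }
    }
    // SE backward
    arma::mat dgate = group_sums_prod_cpp(dse, a, hw);
    arma::mat dz2 = dgate % gate % (1.0 - gate);
    arma::mat dW2 = cache->a1[k].t() * dz2;
    arma::rowvec db2 = arma::sum(dz2, 0);
    arma::mat da1 = dz2 * W2.t();
    arma::mat dz1 = da1 % arma::conv_to<arma::mat>::from(cache->a1[k] > 0);
    arma::mat dW1 = cache->s[k].t() * dz1;
    arma::rowvec db1 = arma::sum(dz1, 0);
    arma::mat ds = dz1 * W1.t();
    arma::mat dconv = group_scale_affine_cpp(dse, gate, ds / hw, hw);
    // ReLU backward (a holds post-ReLU values)
    const double* ap = a.memptr();
    double* dp = dconv.memptr();
    const size_t nel = a.n_elem;
    for (size_t i = 0; i < nel; ++i)
      if (ap[i] <= 0) dp[i] = 0.0;
    // conv backward (im2col input cached from the forward pass)
    const arma::mat& Xcol = cache->xcol[k];
    arma::mat dW = Xcol.t() * dconv;
    arma::rowvec db = arma::sum(dconv, 0);
    if (k > 0) {
      const int cin = W.n_rows / 9;
      arma::mat dXcol = dconv * W.t();
      arma::mat dxin(static_cast<arma::uword>(hw) * N, cin, arma::fill::zeros);
      for (int o = 0; o < 9; ++o) {
        const int di = o % 3 - 1, dj = o / 3 - 1;
        for (int c = 0; c < cin; ++c) {
          const double* src = dXcol.colptr(o * cin + c);
          double* dst = dxin.colptr(c);
          for (int nn = 0; nn < N; ++nn)
            for (int j = 0; j < w; ++j) {
              const int js = j + dj;
              if (js < 0 || js >= w) continue;
              const double* sp = src + static_cast<size_t>(nn) * hw +
                static_cast<size_t>(j) * h;
              double* dd = dst + static_cast<size_t>(nn) * hw +
                static_cast<size_t>(js) * h;
              const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
              for (int i = i0; i < i1; ++i) dd[i + di] += sp[i];
            }
        }
      }
      dx = std::move(dxin);
    }
    grads[6 * k] = dW;
    grads[6 * k + 1] = NumericVector(db.begin(), db.end());
    grads[6 * k + 2] = dW1;
    grads[6 * k + 3] = NumericVector(db1.begin(), db1.end());
    grads[6 * k + 4] = dW2;
    grads[6 * k + 5] = NumericVector(db2.begin(), db2.end());
  }
  return grads;
}
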