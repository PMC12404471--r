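// Neural-network compute core: im2col/GEMM convolutions, ConvLSTM recurrence
// with dual convolutional heads (frame predictor), and a vanilla U-Net
// encoder-decoder (embryo cropper), each exposed as a pure function
// parameter-vector -> (loss, gradient, outputs) so optimization and
// numerical gradient checking stay on the R side.
//
// Array conventions: images are Cube<T> with rows = H, cols = W,
// slices = channels, matching R's dim = c(H, W, C) column-major layout.
// Because an (H, W, C) cube is memory-identical to an (H*W, C) column-major
// matrix, feature maps are aliased as such matrices (zero copy) and all
// convolutions run as (H*W x C*k*k) * (C*k*k x Cout) GEMMs.
// Convolutions use odd kernels with "same" zero padding.
//
// Everything is templated on the floating type: double for exactness
// (gradient checks) and float for training throughput; the `precision`
// field of the config selects the instantiation ("single" or "double").

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

template <typename T> using TMat = arma::Mat<T>;
template <typename T> using TVec = arma::Col<T>;
template <typename T> using TCube = arma::Cube<T>;

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------

template <typename T>
static inline TCube<T> sigmoid_c(const TCube<T>& x) {
  return T(1) / (T(1) + arma::exp(-x));
}

template <typename T>
static inline TCube<T> act_c(const TCube<T>& x, bool relu) {
  if (relu) return arma::clamp(x, T(0), std::numeric_limits<T>::infinity());
  return arma::tanh(x);
}

// derivative of the cell activation evaluated from the *pre-activation*
template <typename T>
static inline TCube<T> actp_c(const TCube<T>& x, bool relu) {
  if (relu) return arma::conv_to<TCube<T>>::from(x > T(0));
  TCube<T> t = arma::tanh(x);
  return T(1) - t % t;
}

// zero-copy view of a cube as an (H*W x C) matrix
template <typename T>
static inline TMat<T> asmat(const TCube<T>& X) {
  return TMat<T>(const_cast<T*>(X.memptr()), X.n_rows * X.n_cols, X.n_slices,
                 false, true);
}

template <typename T>
static inline TCube<T> ascube(const TMat<T>& M, int H, int W) {
  TCube<T> out(H, W, M.n_cols);
  std::memcpy(out.memptr(), M.memptr(), sizeof(T) * M.n_elem);
  return out;
}

template <typename T>
static TCube<T> cube_from_R(const NumericVector& x, int H, int W, int C,
                            size_t offset = 0) {
  TCube<T> out(H, W, C);
  const double* src = x.begin() + offset;
  T* dst = out.memptr();
  const size_t n = (size_t)H * W * C;
  for (size_t i = 0; i < n; ++i) dst[i] = (T)src[i];
  return out;
}

template <typename T>
static NumericVector cube_to_R(const TCube<T>& X) {
  NumericVector out(X.n_elem);
  const T* src = X.memptr();
  for (size_t i = 0; i < (size_t)X.n_elem; ++i) out[i] = (double)src[i];
  return out;
}

// im2col (transposed layout) for same-padding convolution with odd kernel k.
// Output: (H*W) x (C*k*k); row index j*H + i for output pixel (i, j),
// column index c*k*k + dj*k + di. Contiguous writes along i.
template <typename T>
static TMat<T> im2col(const TCube<T>& X, int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = (k - 1) / 2;
  TMat<T> M(H * W, C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        T* dst = M.colptr(r);
        const T* src = X.slice_memptr(c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          const T* s = src + (size_t)sj * H + (i0 + di - p);
          std::memcpy(dst + (size_t)j * H + i0, s, sizeof(T) * (i1 - i0));
        }
      }
    }
  }
  return M;
}

// adjoint of im2col: scatter-add column-matrix gradients back to image grads
template <typename T>
static TCube<T> col2im(const TMat<T>& dM, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  TCube<T> dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const T* src = dM.colptr(r);
        T* dst = dX.slice_memptr(c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          T* d = dst + (size_t)sj * H + (i0 + di - p);
          const T* s = src + (size_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dX;
}

// W is stored (Cout x C*k*k); returns (H, W, Cout)
template <typename T>
static TCube<T> conv_fw(const TCube<T>& X, const TMat<T>& Wm, const TVec<T>& b,
                        int k, TMat<T>* keepM = nullptr) {
  TMat<T> M = im2col(X, k);
  TMat<T> Yt = M * Wm.t();
  Yt.each_row() += b.t();
  TCube<T> out = ascube(Yt, X.n_rows, X.n_cols);
  if (keepM) *keepM = std::move(M);
  return out;
}

// parameter views into a flat vector of the working precision (no copies)
template <typename T>
struct ParCursor {
  T* p;
  arma::uword off, total;
  ParCursor(T* p_, arma::uword total_) : p(p_), off(0), total(total_) {}
  TMat<T> matv(int r, int c) {
    TMat<T> m(p + off, r, c, false, true);
    off += (arma::uword)r * c;
    return m;
  }
  TVec<T> vecv(int n) {
    TVec<T> v(p + off, n, false, true);
    off += n;
    return v;
  }
};

static bool single_precision(const List& cfg) {
  if (!cfg.containsElementNamed("precision")) return false;
  return as<std::string>(cfg["precision"]) == "single";
}

template <typename T>
static TVec<T> par_from_R(const NumericVector& par) {
  TVec<T> out(par.size());
  for (int i = 0; i < par.size(); ++i) out[i] = (T)par[i];
  return out;
}

// ---------------------------------------------------------------------------
// FramePredictor: 4 ConvLSTM layers (+ per-timestep channel normalization
// after the first three), dropout on the last hidden state, two parallel
// sigmoid convolution heads, summed mean binary cross entropy.
// ---------------------------------------------------------------------------

struct FpCfg {
  int H, W, C, F, hk;
  arma::ivec nh, ks;
  bool relu;
};

static FpCfg fp_cfg(const List& cfg) {
  FpCfg c;
  c.H = as<int>(cfg["H"]); c.W = as<int>(cfg["W"]);
  c.C = as<int>(cfg["C"]); c.F = as<int>(cfg["F"]);
  c.nh = as<arma::ivec>(cfg["filters"]);
  c.ks = as<arma::ivec>(cfg["kernels"]);
  c.hk = as<int>(cfg["head_kernel"]);
  std::string a = as<std::string>(cfg["activation"]);
  c.relu = (a == "relu");
  if (c.nh.n_elem != 4 || c.ks.n_elem != 4) stop("need 4 filter widths and 4 kernel sizes");
  return c;
}

// [[Rcpp::export]]
List cpp_fp_shapes(List cfg) {
  FpCfg c = fp_cfg(cfg);
  List out;
  for (int l = 0; l < 4; ++l) {
    int cin = (l == 0) ? c.C : (int)c.nh[l - 1];
    int k = (int)c.ks[l], nh = (int)c.nh[l];
    out.push_back(IntegerVector::create(4 * nh, (cin + nh) * k * k),
                  "lstm" + std::to_string(l + 1) + "_W");
    out.push_back(IntegerVector::create(4 * nh, 1), "lstm" + std::to_string(l + 1) + "_b");
  }
  for (int l = 0; l < 3; ++l) {
    out.push_back(IntegerVector::create((int)c.nh[l], 1), "norm" + std::to_string(l + 1) + "_gamma");
    out.push_back(IntegerVector::create((int)c.nh[l], 1), "norm" + std::to_string(l + 1) + "_beta");
  }
  out.push_back(IntegerVector::create(c.C, c.nh[3] * c.hk * c.hk), "head1_W");
  out.push_back(IntegerVector::create(c.C, 1), "head1_b");
  out.push_back(IntegerVector::create(3, (int)c.nh[3] * c.hk * c.hk), "head2_W");
  out.push_back(IntegerVector::create(3, 1), "head2_b");
  return out;
}

template <typename T>
struct NormCache {
  TVec<T> mu, inv;  // per-channel statistics over H*W
};

// per-timestep, per-channel normalization over the spatial plane
template <typename T>
static TCube<T> norm_fw(const TCube<T>& x, const TVec<T>& gamma,
                        const TVec<T>& beta, NormCache<T>& nc) {
  const int C = x.n_slices;
  const T eps = (T)1e-5;
  TCube<T> y(x.n_rows, x.n_cols, C);
  nc.mu.set_size(C); nc.inv.set_size(C);
  for (int c = 0; c < C; ++c) {
    T m = arma::mean(arma::vectorise(x.slice(c)));
    T v = arma::mean(arma::square(arma::vectorise(x.slice(c)) - m));
    T inv = T(1) / std::sqrt(v + eps);
    nc.mu[c] = m; nc.inv[c] = inv;
    y.slice(c) = gamma[c] * ((x.slice(c) - m) * inv) + beta[c];
  }
  return y;
}

template <typename T>
static TCube<T> norm_bw(const TCube<T>& dy, const TCube<T>& x,
                        const TVec<T>& gamma, const NormCache<T>& nc,
                        TVec<T>& dgamma, TVec<T>& dbeta) {
  const int C = x.n_slices;
  TCube<T> dx(x.n_rows, x.n_cols, C);
  for (int c = 0; c < C; ++c) {
    TMat<T> xhat = (x.slice(c) - nc.mu[c]) * nc.inv[c];
    dgamma[c] += arma::accu(dy.slice(c) % xhat);
    dbeta[c] += arma::accu(dy.slice(c));
    TMat<T> dxh = dy.slice(c) * gamma[c];
    T m1 = arma::mean(arma::vectorise(dxh));
    T m2 = arma::mean(arma::vectorise(dxh % xhat));
    dx.slice(c) = nc.inv[c] * (dxh - m1 - xhat * m2);
  }
  return dx;
}

template <typename T>
static double bce_mean(const TCube<T>& p, const TCube<T>& y) {
  const T eps = (T)1e-7;
  TCube<T> pc = arma::clamp(p, eps, T(1) - eps);
  return -(double)arma::accu(y % arma::log(pc) +
                             (T(1) - y) % arma::log(T(1) - pc)) /
         (double)p.n_elem;
}

template <typename T>
static List fp_run_impl(const NumericVector& par, const List& cfg,
                        const NumericVector& x,
                        const Nullable<NumericVector>& dropmask,
                        const Nullable<NumericVector>& y_full,
                        const Nullable<NumericVector>& y_img,
                        bool want_grad) {
  FpCfg c = fp_cfg(cfg);
  const int H = c.H, W = c.W, Tn = c.F;

  TVec<T> parv = par_from_R<T>(par);
  ParCursor<T> pc(parv.memptr(), parv.n_elem);
  std::vector<TMat<T>> Wl(4); std::vector<TVec<T>> bl(4);
  for (int l = 0; l < 4; ++l) {
    int cin = (l == 0) ? c.C : (int)c.nh[l - 1];
    int k = (int)c.ks[l], nh = (int)c.nh[l];
    Wl[l] = pc.matv(4 * nh, (cin + nh) * k * k);
    bl[l] = pc.vecv(4 * nh);
  }
  std::vector<TVec<T>> gam(3), bet(3);
  for (int l = 0; l < 3; ++l) { gam[l] = pc.vecv((int)c.nh[l]); bet[l] = pc.vecv((int)c.nh[l]); }
  TMat<T> Wh1 = pc.matv(c.C, (int)c.nh[3] * c.hk * c.hk); TVec<T> bh1 = pc.vecv(c.C);
  TMat<T> Wh2 = pc.matv(3, (int)c.nh[3] * c.hk * c.hk); TVec<T> bh2 = pc.vecv(3);
  if (pc.off != (arma::uword)parv.n_elem) stop("parameter vector length mismatch");

  // unpack input sequence
  std::vector<TCube<T>> seq(Tn);
  const size_t fr = (size_t)H * W * c.C;
  for (int t = 0; t < Tn; ++t) seq[t] = cube_from_R<T>(x, H, W, c.C, t * fr);

  // caches (im2col matrices are kept only when gradients are requested)
  std::vector<std::vector<TCube<T>>> inseq(4), Ig(4), Fg(4), Og(4), Gg(4),
      Cs(4), Hs(4), Nout(3);
  std::vector<std::vector<TMat<T>>> Mcache(4);
  std::vector<std::vector<NormCache<T>>> ncache(3);

  std::vector<TCube<T>> cur = seq;
  for (int l = 0; l < 4; ++l) {
    const int nh = (int)c.nh[l], k = (int)c.ks[l];
    inseq[l] = cur;
    Ig[l].resize(Tn); Fg[l].resize(Tn); Og[l].resize(Tn); Gg[l].resize(Tn);
    Cs[l].resize(Tn); Hs[l].resize(Tn);
    if (want_grad) Mcache[l].resize(Tn);
    TCube<T> h(H, W, nh, arma::fill::zeros), cs(H, W, nh, arma::fill::zeros);
    std::vector<TCube<T>> out(Tn);
    for (int t = 0; t < Tn; ++t) {
      TCube<T> in = arma::join_slices(cur[t], h);
      TCube<T> Zc = conv_fw<T>(in, Wl[l], bl[l], k,
                               want_grad ? &Mcache[l][t] : nullptr);
      TCube<T> i_ = sigmoid_c<T>(Zc.slices(0, nh - 1));
      TCube<T> f_ = sigmoid_c<T>(Zc.slices(nh, 2 * nh - 1));
      TCube<T> o_ = sigmoid_c<T>(Zc.slices(2 * nh, 3 * nh - 1));
      TCube<T> g_ = act_c<T>(Zc.slices(3 * nh, 4 * nh - 1), c.relu);
      cs = f_ % cs + i_ % g_;
      h = o_ % act_c<T>(cs, c.relu);
      Ig[l][t] = i_; Fg[l][t] = f_; Og[l][t] = o_; Gg[l][t] = g_;
      Cs[l][t] = cs; Hs[l][t] = h;
      out[t] = h;
    }
    if (l < 3) {
      Nout[l].resize(Tn); ncache[l].resize(Tn);
      for (int t = 0; t < Tn; ++t)
        Nout[l][t] = norm_fw<T>(out[t], gam[l], bet[l], ncache[l][t]);
      cur = Nout[l];
    } else {
      cur.assign(1, out[Tn - 1]);
    }
  }

  // dropout on the final hidden state
  TCube<T> mask;
  if (dropmask.isNotNull()) {
    NumericVector dm(dropmask.get());
    mask = cube_from_R<T>(dm, H, W, (int)c.nh[3]);
  } else {
    mask = TCube<T>(H, W, (int)c.nh[3], arma::fill::ones);
  }
  TCube<T> hdrop = cur[0] % mask;

  // heads
  TMat<T> Mh = im2col<T>(hdrop, c.hk);
  TMat<T> P1 = Mh * Wh1.t(); P1.each_row() += bh1.t();
  TMat<T> P2 = Mh * Wh2.t(); P2.each_row() += bh2.t();
  TCube<T> p1 = sigmoid_c<T>(ascube<T>(P1, H, W));
  TCube<T> p2 = sigmoid_c<T>(ascube<T>(P2, H, W));

  double loss = NA_REAL;
  TCube<T> yf, yi;
  bool have_y = y_full.isNotNull() && y_img.isNotNull();
  if (have_y) {
    NumericVector yfv(y_full.get()), yiv(y_img.get());
    yf = cube_from_R<T>(yfv, H, W, c.C);
    yi = cube_from_R<T>(yiv, H, W, 3);
    loss = bce_mean<T>(p1, yf) + bce_mean<T>(p2, yi);
  }

  List out = List::create(
    _["loss"] = loss,
    _["head1"] = cube_to_R<T>(p1),
    _["head2"] = cube_to_R<T>(p2));
  out.attr("dims") = IntegerVector::create(H, W, c.C);
  if (!want_grad) return out;
  if (!have_y) stop("gradients require targets");

  // ---- backward ----
  TVec<T> gradv(parv.n_elem, arma::fill::zeros);
  ParCursor<T> gc(gradv.memptr(), gradv.n_elem);
  std::vector<TMat<T>> dWl(4); std::vector<TVec<T>> dbl(4);
  for (int l = 0; l < 4; ++l) {
    int cin = (l == 0) ? c.C : (int)c.nh[l - 1];
    int k = (int)c.ks[l], nh = (int)c.nh[l];
    dWl[l] = gc.matv(4 * nh, (cin + nh) * k * k);
    dbl[l] = gc.vecv(4 * nh);
  }
  std::vector<TVec<T>> dgam(3), dbet(3);
  for (int l = 0; l < 3; ++l) { dgam[l] = gc.vecv((int)c.nh[l]); dbet[l] = gc.vecv((int)c.nh[l]); }
  TMat<T> dWh1 = gc.matv(c.C, (int)c.nh[3] * c.hk * c.hk); TVec<T> dbh1 = gc.vecv(c.C);
  TMat<T> dWh2 = gc.matv(3, (int)c.nh[3] * c.hk * c.hk); TVec<T> dbh2 = gc.vecv(3);

  // heads: d(loss)/d(pre-sigmoid) = (p - y) / n for mean BCE
  TCube<T> dpre1 = (p1 - yf) / (T)p1.n_elem;
  TCube<T> dpre2 = (p2 - yi) / (T)p2.n_elem;
  TMat<T> dP1 = asmat<T>(dpre1), dP2 = asmat<T>(dpre2);
  dWh1 += dP1.t() * Mh; dbh1 += arma::sum(dP1, 0).t();
  dWh2 += dP2.t() * Mh; dbh2 += arma::sum(dP2, 0).t();
  TMat<T> dMh = dP1 * Wh1 + dP2 * Wh2;
  TCube<T> dhdrop = col2im<T>(dMh, H, W, (int)c.nh[3], c.hk);
  TCube<T> dlast = dhdrop % mask;

  // BPTT through the stack
  std::vector<TCube<T>> dupper(Tn);  // grad wrt this layer's outputs
  for (int l = 3; l >= 0; --l) {
    const int nh = (int)c.nh[l], k = (int)c.ks[l];
    const int cin = (l == 0) ? c.C : (int)c.nh[l - 1];
    std::vector<TCube<T>> dh_out(Tn);
    if (l == 3) {
      for (int t = 0; t < Tn; ++t) dh_out[t] = TCube<T>(H, W, nh, arma::fill::zeros);
      dh_out[Tn - 1] = dlast;
    } else {
      for (int t = 0; t < Tn; ++t)
        dh_out[t] = norm_bw<T>(dupper[t], Hs[l][t], gam[l], ncache[l][t],
                               dgam[l], dbet[l]);
    }
    std::vector<TCube<T>> dlow(Tn);
    TCube<T> dh_rec(H, W, nh, arma::fill::zeros), dc(H, W, nh, arma::fill::zeros);
    for (int t = Tn - 1; t >= 0; --t) {
      TCube<T> dh = dh_out[t] + dh_rec;
      const TCube<T>& i_ = Ig[l][t]; const TCube<T>& f_ = Fg[l][t];
      const TCube<T>& o_ = Og[l][t]; const TCube<T>& g_ = Gg[l][t];
      const TCube<T>& cs = Cs[l][t];
      TCube<T> do_ = dh % act_c<T>(cs, c.relu);
      dc += dh % o_ % actp_c<T>(cs, c.relu);
      TCube<T> cprev = (t == 0) ? TCube<T>(H, W, nh, arma::fill::zeros)
                                : Cs[l][t - 1];
      TCube<T> di = dc % g_;
      TCube<T> dg = dc % i_;
      TCube<T> df = dc % cprev;
      dc = dc % f_;  // becomes dc for t-1
      // pre-activation grads
      TCube<T> dZ(H, W, 4 * nh);
      dZ.slices(0, nh - 1) = di % i_ % (T(1) - i_);
      dZ.slices(nh, 2 * nh - 1) = df % f_ % (T(1) - f_);
      dZ.slices(2 * nh, 3 * nh - 1) = do_ % o_ % (T(1) - o_);
      if (c.relu) {
        dZ.slices(3 * nh, 4 * nh - 1) = dg % arma::conv_to<TCube<T>>::from(g_ > T(0));
      } else {
        dZ.slices(3 * nh, 4 * nh - 1) = dg % (T(1) - g_ % g_);
      }
      TMat<T> dZm = asmat<T>(dZ);
      const TMat<T>& M = Mcache[l][t];
      dWl[l] += dZm.t() * M;
      dbl[l] += arma::sum(dZm, 0).t();
      TCube<T> dIn = col2im<T>(dZm * Wl[l], H, W, cin + nh, k);
      dlow[t] = dIn.slices(0, cin - 1);
      dh_rec = dIn.slices(cin, cin + nh - 1);
    }
    dupper = dlow;
  }

  NumericVector gout(gradv.n_elem);
  for (size_t i = 0; i < (size_t)gradv.n_elem; ++i) gout[i] = (double)gradv[i];
  out["grad"] = gout;
  return out;
}

// Full forward (and optionally backward) pass for one sample.
// x: array (H, W, C, F). dropmask: (H, W, nh4), already scaled by 1/(1-rate)
// (all ones for inference). y_full (H, W, C) / y_img (H, W, 3) optional.
// [[Rcpp::export]]
List cpp_fp_run(NumericVector par, List cfg, NumericVector x,
                Nullable<NumericVector> dropmask,
                Nullable<NumericVector> y_full, Nullable<NumericVector> y_img,
                bool want_grad) {
  if (single_precision(cfg)) {
    return fp_run_impl<float>(par, cfg, x, dropmask, y_full, y_img, want_grad);
  }
  return fp_run_impl<double>(par, cfg, x, dropmask, y_full, y_img, want_grad);
}

// ---------------------------------------------------------------------------
// standalone convolution (exposed for oracle tests; double precision)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericMatrix w, NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  arma::cube X(x.begin(), d[0], d[1], d.size() == 3 ? d[2] : 1);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol());
  arma::vec bv(b.begin(), b.size());
  arma::cube Y = conv_fw<double>(X, Wm, bv, k);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Y.n_rows, Y.n_cols, Y.n_slices);
  return out;
}

// ---------------------------------------------------------------------------
// U-Net embryo cropper
// ---------------------------------------------------------------------------

struct UnCfg {
  int H, W, Cin, depth, base, K;
};

static UnCfg un_cfg(const List& cfg) {
  UnCfg c;
  c.H = as<int>(cfg["H"]); c.W = as<int>(cfg["W"]);
  c.Cin = as<int>(cfg["Cin"]); c.depth = as<int>(cfg["depth"]);
  c.base = as<int>(cfg["base"]); c.K = as<int>(cfg["nclasses"]);
  int div = 1 << c.depth;
  if (c.H % div != 0 || c.W % div != 0) stop("spatial size must be divisible by 2^depth");
  return c;
}

// [[Rcpp::export]]
List cpp_unet_shapes(List cfg) {
  UnCfg c = un_cfg(cfg);
  List out;
  auto f = [&](int i) { return c.base << i; };
  for (int i = 0; i < c.depth; ++i) {
    int cin = (i == 0) ? c.Cin : f(i - 1);
    out.push_back(IntegerVector::create(f(i), cin * 9), "enc" + std::to_string(i) + "A_W");
    out.push_back(IntegerVector::create(f(i), 1), "enc" + std::to_string(i) + "A_b");
    out.push_back(IntegerVector::create(f(i), f(i) * 9), "enc" + std::to_string(i) + "B_W");
    out.push_back(IntegerVector::create(f(i), 1), "enc" + std::to_string(i) + "B_b");
  }
  out.push_back(IntegerVector::create(f(c.depth), f(c.depth - 1) * 9), "botA_W");
  out.push_back(IntegerVector::create(f(c.depth), 1), "botA_b");
  out.push_back(IntegerVector::create(f(c.depth), f(c.depth) * 9), "botB_W");
  out.push_back(IntegerVector::create(f(c.depth), 1), "botB_b");
  for (int i = c.depth - 1; i >= 0; --i) {
    int gin = (i == c.depth - 1) ? f(c.depth) : f(i + 1);
    out.push_back(IntegerVector::create(f(i), gin * 9), "up" + std::to_string(i) + "_W");
    out.push_back(IntegerVector::create(f(i), 1), "up" + std::to_string(i) + "_b");
    out.push_back(IntegerVector::create(f(i), 2 * f(i) * 9), "dec" + std::to_string(i) + "A_W");
    out.push_back(IntegerVector::create(f(i), 1), "dec" + std::to_string(i) + "A_b");
    out.push_back(IntegerVector::create(f(i), f(i) * 9), "dec" + std::to_string(i) + "B_W");
    out.push_back(IntegerVector::create(f(i), 1), "dec" + std::to_string(i) + "B_b");
  }
  out.push_back(IntegerVector::create(c.K, f(0)), "final_W");
  out.push_back(IntegerVector::create(c.K, 1), "final_b");
  return out;
}

template <typename T>
static TCube<T> maxpool2(const TCube<T>& x, arma::ucube& idx) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  TCube<T> y(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        T best = x(2 * i, 2 * j, c); arma::uword bi = 0;
        T v;
        v = x(2 * i + 1, 2 * j, c); if (v > best) { best = v; bi = 1; }
        v = x(2 * i, 2 * j + 1, c); if (v > best) { best = v; bi = 2; }
        v = x(2 * i + 1, 2 * j + 1, c); if (v > best) { best = v; bi = 3; }
        y(i, j, c) = best; idx(i, j, c) = bi;
      }
  return y;
}

template <typename T>
static TCube<T> maxpool2_bw(const TCube<T>& dy, const arma::ucube& idx) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  TCube<T> dx(2 * H, 2 * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        arma::uword bi = idx(i, j, c);
        dx(2 * i + (bi == 1 || bi == 3), 2 * j + (bi >= 2), c) = dy(i, j, c);
      }
  return dx;
}

template <typename T>
static TCube<T> upsample2(const TCube<T>& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  TCube<T> y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        T v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

template <typename T>
static TCube<T> upsample2_bw(const TCube<T>& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  TCube<T> dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

template <typename T>
struct ConvCache { TCube<T> in, out; TMat<T> M; };  // out is post-ReLU

template <typename T>
static TCube<T> conv_relu_fw(const TCube<T>& x, const TMat<T>& Wm,
                             const TVec<T>& b, ConvCache<T>& cc, bool keep) {
  TCube<T> y = conv_fw<T>(x, Wm, b, 3, keep ? &cc.M : nullptr);
  cc.out = arma::clamp(y, T(0), std::numeric_limits<T>::infinity());
  if (keep) cc.in = x;
  return cc.out;
}

template <typename T>
static TCube<T> conv_relu_bw(const TCube<T>& dy, const TMat<T>& Wm,
                             TMat<T>& dW, TVec<T>& db, const ConvCache<T>& cc) {
  TCube<T> d = dy % arma::conv_to<TCube<T>>::from(cc.out > T(0));
  TMat<T> dm = asmat<T>(d);
  dW += dm.t() * cc.M;
  db += arma::sum(dm, 0).t();
  return col2im<T>(dm * Wm, cc.in.n_rows, cc.in.n_cols, cc.in.n_slices, 3);
}

template <typename T>
static List unet_run_impl(const NumericVector& par, const List& cfg,
                          const NumericVector& x,
                          const Nullable<IntegerMatrix>& labels,
                          bool want_grad) {
  UnCfg c = un_cfg(cfg);
  auto f = [&](int i) { return c.base << i; };
  const int D = c.depth;

  TVec<T> parv = par_from_R<T>(par);
  ParCursor<T> pc(parv.memptr(), parv.n_elem);
  std::vector<TMat<T>> eAW(D), eBW(D), upW(D), dAW(D), dBW(D);
  std::vector<TVec<T>> eAb(D), eBb(D), upb(D), dAb(D), dBb(D);
  for (int i = 0; i < D; ++i) {
    int cin = (i == 0) ? c.Cin : f(i - 1);
    eAW[i] = pc.matv(f(i), cin * 9); eAb[i] = pc.vecv(f(i));
    eBW[i] = pc.matv(f(i), f(i) * 9); eBb[i] = pc.vecv(f(i));
  }
  TMat<T> bAW = pc.matv(f(D), f(D - 1) * 9); TVec<T> bAb = pc.vecv(f(D));
  TMat<T> bBW = pc.matv(f(D), f(D) * 9); TVec<T> bBb = pc.vecv(f(D));
  for (int i = D - 1; i >= 0; --i) {
    int gin = (i == D - 1) ? f(D) : f(i + 1);
    upW[i] = pc.matv(f(i), gin * 9); upb[i] = pc.vecv(f(i));
    dAW[i] = pc.matv(f(i), 2 * f(i) * 9); dAb[i] = pc.vecv(f(i));
    dBW[i] = pc.matv(f(i), f(i) * 9); dBb[i] = pc.vecv(f(i));
  }
  TMat<T> fW = pc.matv(c.K, f(0)); TVec<T> fb = pc.vecv(c.K);
  if (pc.off != (arma::uword)parv.n_elem) stop("parameter vector length mismatch");

  IntegerVector xd = x.attr("dim");
  if (xd[0] != c.H || xd[1] != c.W ||
      (xd.size() == 3 ? xd[2] : 1) != c.Cin)
    stop("input shape does not match the model configuration");
  TCube<T> X = cube_from_R<T>(x, c.H, c.W, c.Cin);

  // encoder
  std::vector<ConvCache<T>> ceA(D), ceB(D), cdU(D), cdA(D), cdB(D);
  ConvCache<T> cbA, cbB;
  std::vector<TCube<T>> skips(D);
  std::vector<arma::ucube> pidx(D);
  TCube<T> cur = X;
  for (int i = 0; i < D; ++i) {
    cur = conv_relu_fw<T>(cur, eAW[i], eAb[i], ceA[i], want_grad);
    cur = conv_relu_fw<T>(cur, eBW[i], eBb[i], ceB[i], want_grad);
    skips[i] = cur;
    cur = maxpool2<T>(cur, pidx[i]);
  }
  cur = conv_relu_fw<T>(cur, bAW, bAb, cbA, want_grad);
  cur = conv_relu_fw<T>(cur, bBW, bBb, cbB, want_grad);
  // decoder
  for (int i = D - 1; i >= 0; --i) {
    cur = upsample2<T>(cur);
    cur = conv_relu_fw<T>(cur, upW[i], upb[i], cdU[i], want_grad);
    cur = arma::join_slices(skips[i], cur);
    cur = conv_relu_fw<T>(cur, dAW[i], dAb[i], cdA[i], want_grad);
    cur = conv_relu_fw<T>(cur, dBW[i], dBb[i], cdB[i], want_grad);
  }
  // 1x1 head + softmax (logits kept as (H*W x K))
  TMat<T> logits = asmat<T>(cur) * fW.t();
  logits.each_row() += fb.t();
  TVec<T> lmax = arma::max(logits, 1);
  TMat<T> el = arma::exp(logits.each_col() - lmax);
  TVec<T> rs = arma::sum(el, 1);
  TMat<T> probs = el.each_col() / rs;

  double loss = NA_REAL;
  const int n = c.H * c.W;
  IntegerMatrix lab;
  if (labels.isNotNull()) {
    lab = labels.get();
    double s = 0.0;
    for (int j = 0; j < c.W; ++j)
      for (int i = 0; i < c.H; ++i) {
        int k = lab(i, j);
        s -= std::log(std::max((double)probs(j * c.H + i, k), 1e-12));
      }
    loss = s / n;
  }

  TCube<T> pr = ascube<T>(probs, c.H, c.W);
  List out = List::create(_["loss"] = loss, _["probs"] = cube_to_R<T>(pr));
  out.attr("pdim") = IntegerVector::create(c.H, c.W, c.K);
  if (!want_grad) return out;
  if (labels.isNull()) stop("gradients require labels");

  TVec<T> gradv(parv.n_elem, arma::fill::zeros);
  ParCursor<T> gc(gradv.memptr(), gradv.n_elem);
  std::vector<TMat<T>> geAW(D), geBW(D), gupW(D), gdAW(D), gdBW(D);
  std::vector<TVec<T>> geAb(D), geBb(D), gupb(D), gdAb(D), gdBb(D);
  for (int i = 0; i < D; ++i) {
    int cin = (i == 0) ? c.Cin : f(i - 1);
    geAW[i] = gc.matv(f(i), cin * 9); geAb[i] = gc.vecv(f(i));
    geBW[i] = gc.matv(f(i), f(i) * 9); geBb[i] = gc.vecv(f(i));
  }
  TMat<T> gbAW = gc.matv(f(D), f(D - 1) * 9); TVec<T> gbAb = gc.vecv(f(D));
  TMat<T> gbBW = gc.matv(f(D), f(D) * 9); TVec<T> gbBb = gc.vecv(f(D));
  for (int i = D - 1; i >= 0; --i) {
    int gin = (i == D - 1) ? f(D) : f(i + 1);
    gupW[i] = gc.matv(f(i), gin * 9); gupb[i] = gc.vecv(f(i));
    gdAW[i] = gc.matv(f(i), 2 * f(i) * 9); gdAb[i] = gc.vecv(f(i));
    gdBW[i] = gc.matv(f(i), f(i) * 9); gdBb[i] = gc.vecv(f(i));
  }
  TMat<T> gfW = gc.matv(c.K, f(0)); TVec<T> gfb = gc.vecv(c.K);

  // softmax + CE
  TMat<T> dlogits = probs;
  for (int j = 0; j < c.W; ++j)
    for (int i = 0; i < c.H; ++i) dlogits(j * c.H + i, lab(i, j)) -= T(1);
  dlogits /= (T)n;
  gfW += dlogits.t() * asmat<T>(cur);
  gfb += arma::sum(dlogits, 0).t();
  TCube<T> dcur = ascube<T>(dlogits * fW, c.H, c.W);

  // decoder side, shallowest level first (reverse of forward order),
  // collecting the gradient flowing into each skip connection
  std::vector<TCube<T>> dskip(D);
  for (int i = 0; i < D; ++i) {
    dcur = conv_relu_bw<T>(dcur, dBW[i], gdBW[i], gdBb[i], cdB[i]);
    dcur = conv_relu_bw<T>(dcur, dAW[i], gdAW[i], gdAb[i], cdA[i]);
    const int fi = f(i);
    dskip[i] = dcur.slices(0, fi - 1);
    TCube<T> dup = dcur.slices(fi, 2 * fi - 1);
    dup = conv_relu_bw<T>(dup, upW[i], gupW[i], gupb[i], cdU[i]);
    dcur = upsample2_bw<T>(dup);  // grad wrt d_{i+1} (or bottleneck output)
  }
  dcur = conv_relu_bw<T>(dcur, bBW, gbBW, gbBb, cbB);
  dcur = conv_relu_bw<T>(dcur, bAW, gbAW, gbAb, cbA);
  // encoder side, deepest level first; dcur is the gradient wrt pool(a_i)
  for (int i = D - 1; i >= 0; --i) {
    TCube<T> da = maxpool2_bw<T>(dcur, pidx[i]) + dskip[i];
    da = conv_relu_bw<T>(da, eBW[i], geBW[i], geBb[i], ceB[i]);
    dcur = conv_relu_bw<T>(da, eAW[i], geAW[i], geAb[i], ceA[i]);
  }

  NumericVector gout(gradv.n_elem);
  for (size_t i = 0; i < (size_t)gradv.n_elem; ++i) gout[i] = (double)gradv[i];
  out["grad"] = gout;
  return out;
}

// Forward (and optionally backward) pass of the U-Net for one image.
// x: (H, W, Cin). labels: integer matrix (H, W) with classes 0..K-1, or NULL.
// [[Rcpp::export]]
List cpp_unet_run(NumericVector par, List cfg, NumericVector x,
                  Nullable<IntegerMatrix> labels, bool want_grad) {
  if (single_precision(cfg)) {
    return unet_run_impl<float>(par, cfg, x, labels, want_grad);
  }
  return unet_run_impl<double>(par, cfg, x, labels, want_grad);
}

// ---------------------------------------------------------------------------
// separable Gaussian filter with replicate ("nearest") edge handling,
// used by the SSIM implementation (double precision)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma, int radius) {
  const int H = img.nrow(), W = img.ncol();
  arma::vec w(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    w(i + radius) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  w /= arma::accu(w);
  arma::mat X(img.begin(), H, W), tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int ii = std::min(std::max(i + d, 0), H - 1);
        s += w(d + radius) * X(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int jj = std::min(std::max(j + d, 0), W - 1);
        s += w(d + radius) * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return NumericMatrix(H, W, out.begin());
}
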