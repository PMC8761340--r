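// Native multi-view CNN engine.
//
// Six branches (3 orthogonal views x 2 pyramid scales), each
//   conv 3x3 (same padding) -> batch norm -> ReLU -> max pool 2x2
//   -> dropout -> dense -> ReLU,
// branch outputs concatenated -> dense ReLU -> dense(2) softmax,
// trained with a batch-level binary soft-dice loss and Adam.
//
// Convolution is im2col + GEMM. The whole engine is templated on the real
// type: float instantiation for training/inference throughput, double
// instantiation backing the finite-difference gradient checks. The conv
// bias is omitted because batch norm follows immediately (its beta makes a
// conv bias exactly redundant). Workspaces persist across batches: the
// large intermediates (im2col matrix, conv activations) are allocated once
// per training run, batch normalization statistics are accumulated in a
// single fused pass, and normalization itself is folded into the pooling
// pass as a per-filter scale and shift of the raw conv activations.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int PATCH = 32;          // in-plane patch size
static const int PAD = 32;            // zero border around each volume
static const int NCH = 3;             // channels: T1, T1gad, STIR
static const int NBRANCH = 6;         // 3 views x 2 scales
static const int NPIX = PATCH * PATCH;        // 1024 conv output pixels
static const int XROWS = NPIX * NCH;          // 3072 rows of a patch block
static const int KK = 9 * NCH;                // 27 im2col rows
static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// ---------------------------------------------------------------- parameters

template <typename T>
struct Net {
  int F, D1, D2;
  T drop;
  arma::Mat<T> Wc[NBRANCH];                   // F x 27
  arma::Col<T> gamma[NBRANCH], beta[NBRANCH]; // F
  arma::Col<T> rmean[NBRANCH], rvar[NBRANCH]; // F (running stats)
  arma::Mat<T> Wd[NBRANCH];                   // D1 x 256F
  arma::Col<T> bd[NBRANCH];                   // D1
  arma::Mat<T> Wh;                            // D2 x 6*D1
  arma::Col<T> bh;                            // D2
  arma::Mat<T> Wo;                            // 2 x D2
  arma::Col<T> bo;                            // 2
};

template <typename T>
static arma::Mat<T> as_matT(SEXP s) {
  NumericMatrix m(s);
  arma::Mat<T> out(m.nrow(), m.ncol());
  const double* src = REAL(m);
  T* dst = out.memptr();
  const size_t n = (size_t)m.nrow() * m.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (T)src[i];
  return out;
}

static NumericMatrix to_rmat(const arma::mat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.memptr(), m.memptr() + m.n_elem, REAL(out));
  return out;
}
static NumericMatrix to_rmat(const arma::fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = REAL(out);
  for (size_t i = 0; i < m.n_elem; ++i) dst[i] = (double)src[i];
  return out;
}

template <typename T>
static Net<T> net_from_r(const List& params, const List& cfg) {
  Net<T> net;
  net.F = as<int>(cfg["conv_filters"]);
  net.D1 = as<int>(cfg["dense_units_branch"]);
  net.D2 = as<int>(cfg["dense_units_head"]);
  net.drop = (T)as<double>(cfg["dropout_rate"]);
  for (int b = 0; b < NBRANCH; ++b) {
    std::string s = std::to_string(b + 1);
    net.Wc[b] = as_matT<T>(params["Wc" + s]);
    net.gamma[b] = arma::vectorise(as_matT<T>(params["gamma" + s]));
    net.beta[b] = arma::vectorise(as_matT<T>(params["beta" + s]));
    net.rmean[b] = arma::vectorise(as_matT<T>(params["rmean" + s]));
    net.rvar[b] = arma::vectorise(as_matT<T>(params["rvar" + s]));
    net.Wd[b] = as_matT<T>(params["Wd" + s]);
    net.bd[b] = arma::vectorise(as_matT<T>(params["bd" + s]));
    if ((int)net.Wc[b].n_rows != net.F || (int)net.Wc[b].n_cols != KK)
      stop("conv weight shape inconsistent with config");
    if ((int)net.Wd[b].n_rows != net.D1 ||
        (int)net.Wd[b].n_cols != net.F * (NPIX / 4))
      stop("branch dense weight shape inconsistent with config");
  }
  net.Wh = as_matT<T>(params["Wh"]);
  net.bh = arma::vectorise(as_matT<T>(params["bh"]));
  net.Wo = as_matT<T>(params["Wo"]);
  net.bo = arma::vectorise(as_matT<T>(params["bo"]));
  if ((int)net.Wh.n_rows != net.D2 || (int)net.Wh.n_cols != NBRANCH * net.D1)
    stop("head dense weight shape inconsistent with config");
  if (net.Wo.n_rows != 2u || (int)net.Wo.n_cols != net.D2)
    stop("output weight shape inconsistent with config");
  return net;
}

template <typename T>
static List net_to_r(const Net<T>& net) {
  List out;
  for (int b = 0; b < NBRANCH; ++b) {
    std::string s = std::to_string(b + 1);
    out["Wc" + s] = to_rmat(net.Wc[b]);
    out["gamma" + s] = to_rmat(arma::Mat<T>(net.gamma[b]));
    out["beta" + s] = to_rmat(arma::Mat<T>(net.beta[b]));
    out["rmean" + s] = to_rmat(arma::Mat<T>(net.rmean[b]));
    out["rvar" + s] = to_rmat(arma::Mat<T>(net.rvar[b]));
    out["Wd" + s] = to_rmat(net.Wd[b]);
    out["bd" + s] = to_rmat(arma::Mat<T>(net.bd[b]));
  }
  out["Wh"] = to_rmat(net.Wh);
  out["bh"] = to_rmat(arma::Mat<T>(net.bh));
  out["Wo"] = to_rmat(net.Wo);
  out["bo"] = to_rmat(arma::Mat<T>(net.bo));
  return out;
}

// Trainable tensors in a fixed order (running stats excluded).
template <typename T>
static void collect_trainables(Net<T>& net, std::vector<arma::Mat<T>*>& ws,
                               std::vector<arma::Col<T>*>& vs,
                               std::vector<std::string>& names) {
  ws.clear(); vs.clear(); names.clear();
  for (int b = 0; b < NBRANCH; ++b) {
    std::string s = std::to_string(b + 1);
    ws.push_back(&net.Wc[b]); vs.push_back(nullptr); names.push_back("Wc" + s);
    ws.push_back(nullptr); vs.push_back(&net.gamma[b]); names.push_back("gamma" + s);
    ws.push_back(nullptr); vs.push_back(&net.beta[b]); names.push_back("beta" + s);
    ws.push_back(&net.Wd[b]); vs.push_back(nullptr); names.push_back("Wd" + s);
    ws.push_back(nullptr); vs.push_back(&net.bd[b]); names.push_back("bd" + s);
  }
  ws.push_back(&net.Wh); vs.push_back(nullptr); names.push_back("Wh");
  ws.push_back(nullptr); vs.push_back(&net.bh); names.push_back("bh");
  ws.push_back(&net.Wo); vs.push_back(nullptr); names.push_back("Wo");
  ws.push_back(nullptr); vs.push_back(&net.bo); names.push_back("bo");
}

// ------------------------------------------------------------ patch gathering

// Write one 32x32 in-plane patch for one channel into dst (layout u + 32*w).
// (ci, cj, ck) are the padded-volume coordinates of the center voxel; the
// center sits at in-window position (16, 16); scale 1 windows span 64 voxels
// and are 2x2 mean-pooled on the fly.
template <typename T>
static void fill_patch(const arma::Cube<T>& V, int ci, int cj, int ck,
                       int view, int scale, T* dst) {
  if (scale == 0) {
    for (int w = 0; w < PATCH; ++w)
      for (int u = 0; u < PATCH; ++u) {
        T val;
        if (view == 0)      val = V(ci - 16 + u, cj - 16 + w, ck);
        else if (view == 1) val = V(ci - 16 + u, cj, ck - 16 + w);
        else                val = V(ci, cj - 16 + u, ck - 16 + w);
        dst[u + PATCH * w] = val;
      }
  } else {
    const T q = (T)0.25;
    for (int w = 0; w < PATCH; ++w)
      for (int u = 0; u < PATCH; ++u) {
        int au = 2 * u, aw = 2 * w;
        T acc = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int du = 0; du < 2; ++du) {
            int uu = au + du, ww = aw + dw;
            if (view == 0)      acc += V(ci - 32 + uu, cj - 32 + ww, ck);
            else if (view == 1) acc += V(ci - 32 + uu, cj, ck - 32 + ww);
            else                acc += V(ci, cj - 32 + uu, ck - 32 + ww);
          }
        dst[u + PATCH * w] = acc * q;
      }
  }
}

// Fill the six patch blocks (XROWS x n each) for a set of sample centers.
// vols: per case, NCH padded cubes; sample centers get the PAD offset here.
template <typename T>
static void build_patch_blocks(
    const std::vector<std::array<arma::Cube<T>, NCH>>& vols,
    const arma::imat& samp, const arma::uvec& idx, arma::Mat<T>* X) {
  const size_t n = idx.n_elem;
  for (int b = 0; b < NBRANCH; ++b) X[b].set_size(XROWS, n);
  for (size_t s = 0; s < n; ++s) {
    const arma::sword r = (arma::sword)idx[s];
    const int cs = (int)samp(r, 0);
    const int ci = (int)samp(r, 1) + PAD, cj = (int)samp(r, 2) + PAD,
              ck = (int)samp(r, 3) + PAD;
    for (int view = 0; view < 3; ++view)
      for (int scale = 0; scale < 2; ++scale) {
        const int b = view * 2 + scale;
        T* colp = X[b].colptr(s);
        for (int ch = 0; ch < NCH; ++ch)
          fill_patch(vols[cs][ch], ci, cj, ck, view, scale, colp + NPIX * ch);
      }
  }
}

// im2col for a 3x3 same-padded convolution over a block of 32x32xNCH patches.
// Output: KK x (NPIX * n); row r = (dx+1) + 3*(dy+1) + 9*ch.
template <typename T>
static void im2col(const arma::Mat<T>& X, arma::Mat<T>& COL) {
  const size_t n = X.n_cols;
  COL.set_size(KK, NPIX * n);
  for (size_t s = 0; s < n; ++s) {
    const T* xp = X.colptr(s);
    for (int w = 0; w < PATCH; ++w) {
      const bool wedge = (w == 0 || w == PATCH - 1);
      T* cp0 = COL.colptr(NPIX * s + PATCH * w);
      // interior pixels: no bounds checks
      for (int u = 1; u < PATCH - 1; ++u) {
        T* cp = cp0 + (size_t)u * KK;
        if (!wedge) {
          for (int ch = 0; ch < NCH; ++ch) {
            const T* b0 = xp + NPIX * ch + (u - 1);
            T* o = cp + 9 * ch;
            const T* rm = b0 + PATCH * (w - 1);
            const T* r0 = b0 + PATCH * w;
            const T* rp = b0 + PATCH * (w + 1);
            o[0] = rm[0]; o[1] = rm[1]; o[2] = rm[2];
            o[3] = r0[0]; o[4] = r0[1]; o[5] = r0[2];
            o[6] = rp[0]; o[7] = rp[1]; o[8] = rp[2];
          }
          continue;
        }
        for (int ch = 0; ch < NCH; ++ch) {
          const T* base = xp + NPIX * ch;
          for (int dy = -1; dy <= 1; ++dy) {
            const int ww = w + dy;
            const bool okw = (ww >= 0 && ww < PATCH);
            for (int dx = -1; dx <= 1; ++dx)
              cp[(dx + 1) + 3 * (dy + 1) + 9 * ch] =
                okw ? base[(u + dx) + PATCH * ww] : (T)0;
          }
        }
      }
      for (int u = 0; u < PATCH; u += PATCH - 1) {   // u edges
        T* cp = cp0 + (size_t)u * KK;
        for (int ch = 0; ch < NCH; ++ch) {
          const T* base = xp + NPIX * ch;
          for (int dy = -1; dy <= 1; ++dy) {
            const int ww = w + dy;
            const bool okw = (ww >= 0 && ww < PATCH);
            for (int dx = -1; dx <= 1; ++dx) {
              const int uu = u + dx;
              T val = 0;
              if (okw && uu >= 0 && uu < PATCH) val = base[uu + PATCH * ww];
              cp[(dx + 1) + 3 * (dy + 1) + 9 * ch] = val;
            }
          }
        }
      }
    }
  }
}

// ------------------------------------------------------------- workspaces

// All large intermediates live here and persist across batches.
template <typename T>
struct Work {
  arma::Mat<T> X[NBRANCH];       // XROWS x n patch blocks
  arma::Mat<T> COL[NBRANCH];     // KK x NPIX*n
  arma::Mat<T> conv[NBRANCH];    // F x NPIX*n raw conv activations
  arma::Col<T> mu[NBRANCH], invstd[NBRANCH];
  arma::Mat<T> pooled[NBRANCH];  // 256F x n (post dropout)
  arma::Mat<T> drop[NBRANCH];    // dropout masks (0 or 1/keep)
  std::vector<uint16_t> win[NBRANCH]; // winning conv pixel per pooled unit
  arma::Mat<T> Z[NBRANCH];       // D1 x n
  arma::Mat<T> ZZ, H1, P;        // head
  arma::Mat<T> dY;               // F x NPIX*n backward scratch
  arma::Mat<T> dlogits, dH1, dZZ, dZ, dpool;
};

template <typename T>
struct Grads {
  arma::Mat<T> Wc[NBRANCH], Wd[NBRANCH];
  arma::Col<T> gamma[NBRANCH], beta[NBRANCH], bd[NBRANCH];
  arma::Mat<T> Wh, Wo;
  arma::Col<T> bh, bo;
};

// ---------------------------------------------------------------- forward

template <typename T>
static void forward_branch(Net<T>& net, int b, Work<T>& w, bool training,
                           std::mt19937_64* rng, bool keep_cache,
                           bool update_running) {
  const int F = net.F;
  const size_t n = w.X[b].n_cols;
  const size_t N = NPIX * n;
  // training caches per branch; inference reuses one scratch slot so the
  // large intermediates are allocated once and stay warm across batches
  const int wi = keep_cache ? b : 0;
  im2col(w.X[b], w.COL[wi]);
  w.conv[wi] = net.Wc[b] * w.COL[wi];             // F x N (raw)
  arma::Mat<T>& conv = w.conv[wi];

  arma::Col<T> mu(F), var(F);
  if (training) {
    // single-pass batch statistics: vector-friendly partial sums per block
    // of columns, accumulated in double across blocks
    arma::Col<double> s1(F, arma::fill::zeros), s2(F, arma::fill::zeros);
    double* s1p = s1.memptr(); double* s2p = s2.memptr();
    std::vector<T> p1(F), p2(F);
    const size_t BLK = 2048;
    for (size_t c0 = 0; c0 < N; c0 += BLK) {
      const size_t c1 = std::min(N, c0 + BLK);
      std::fill(p1.begin(), p1.end(), (T)0);
      std::fill(p2.begin(), p2.end(), (T)0);
      const T* cp = conv.colptr(c0);
      for (size_t c = c0; c < c1; ++c, cp += F)
        for (int f = 0; f < F; ++f) {
          const T v = cp[f];
          p1[f] += v; p2[f] += v * v;
        }
      for (int f = 0; f < F; ++f) {
        s1p[f] += (double)p1[f]; s2p[f] += (double)p2[f];
      }
    }
    for (int f = 0; f < F; ++f) {
      mu[f] = (T)(s1p[f] / (double)N);
      double v = s2p[f] / (double)N - (double)mu[f] * (double)mu[f];
      var[f] = (T)(v < 0 ? 0 : v);
    }
    if (update_running) {
      net.rmean[b] = (T)BN_MOMENTUM * net.rmean[b] + (T)(1.0 - BN_MOMENTUM) * mu;
      net.rvar[b] = (T)BN_MOMENTUM * net.rvar[b] + (T)(1.0 - BN_MOMENTUM) * var;
    }
  } else {
    mu = net.rmean[b];
    var = net.rvar[b];
  }
  arma::Col<T> invstd = (T)1 / arma::sqrt(var + (T)BN_EPS);
  if (keep_cache) { w.mu[b] = mu; w.invstd[b] = invstd; }

  // normalization folded into the pooling pass:
  // a = gamma * (conv - mu) * invstd + beta = alpha * conv + delta
  arma::Col<T> alpha = net.gamma[b] % invstd;
  arma::Col<T> delta = net.beta[b] - net.gamma[b] % mu % invstd;
  const int PR = F * (NPIX / 4);
  w.pooled[wi].set_size(PR, n);
  if (keep_cache) w.win[b].assign((size_t)PR * n, 0);
  const T* alp = alpha.memptr();
  const T* del = delta.memptr();
  for (size_t s = 0; s < n; ++s) {
    T* pp = w.pooled[wi].colptr(s);
    uint16_t* wn = keep_cache ? &w.win[b][(size_t)s * PR] : nullptr;
    for (int pw = 0; pw < PATCH / 2; ++pw)
      for (int pu = 0; pu < PATCH / 2; ++pu) {
        const int q0 = 2 * pu + PATCH * 2 * pw;
        const int qs[4] = {q0, q0 + 1, q0 + PATCH, q0 + PATCH + 1};
        const T* c0 = conv.colptr(NPIX * s + qs[0]);
        const T* c1 = conv.colptr(NPIX * s + qs[1]);
        const T* c2 = conv.colptr(NPIX * s + qs[2]);
        const T* c3 = conv.colptr(NPIX * s + qs[3]);
        const int prow0 = pu + (PATCH / 2) * pw;
        if (wn) {
          for (int f = 0; f < F; ++f) {
            const T a = alp[f], dd = del[f];
            T a0 = a * c0[f] + dd, a1 = a * c1[f] + dd;
            T a2 = a * c2[f] + dd, a3 = a * c3[f] + dd;
            T best = a0; int bi = 0;
            if (a1 > best) { best = a1; bi = 1; }
            if (a2 > best) { best = a2; bi = 2; }
            if (a3 > best) { best = a3; bi = 3; }
            if (best < (T)0) best = (T)0;
            const int prow = prow0 + (NPIX / 4) * f;
            pp[prow] = best;
            wn[prow] = (uint16_t)qs[bi];
          }
        } else {
          // inference: branchless, vectorizable
          for (int f = 0; f < F; ++f) {
            const T a = alp[f], dd = del[f];
            const T m = std::max(std::max(a * c0[f], a * c1[f]),
                                 std::max(a * c2[f], a * c3[f])) + dd;
            pp[prow0 + (NPIX / 4) * f] = m > (T)0 ? m : (T)0;
          }
        }
      }
  }

  if (training && net.drop > (T)0) {
    // dropout decisions from 16-bit lanes of the generator (4 per draw)
    w.drop[wi].set_size(PR, n);
    const T keep = (T)1 - net.drop;
    const T scale = (T)1 / keep;
    const uint64_t thr = (uint64_t)((double)keep * 65536.0);
    T* dm = w.drop[wi].memptr();
    const size_t tot = (size_t)PR * n;
    size_t i = 0;
    while (i < tot) {
      uint64_t bits = (*rng)();
      for (int lane = 0; lane < 4 && i < tot; ++lane, ++i) {
        dm[i] = ((bits & 0xFFFFu) < thr) ? scale : (T)0;
        bits >>= 16;
      }
    }
    w.pooled[wi] %= w.drop[wi];
  } else if (keep_cache) {
    w.drop[b].reset();
  }

  w.Z[b] = net.Wd[b] * w.pooled[wi];
  w.Z[b].each_col() += net.bd[b];
  w.Z[b].transform([](T v) { return v > (T)0 ? v : (T)0; });
  (void)N;
}

template <typename T>
static void forward_head(Net<T>& net, Work<T>& w) {
  const size_t n = w.Z[0].n_cols;
  w.ZZ.set_size(NBRANCH * net.D1, n);
  for (int b = 0; b < NBRANCH; ++b)
    w.ZZ.rows(b * net.D1, (b + 1) * net.D1 - 1) = w.Z[b];
  w.H1 = net.Wh * w.ZZ;
  w.H1.each_col() += net.bh;
  w.H1.transform([](T v) { return v > (T)0 ? v : (T)0; });
  arma::Mat<T> logits = net.Wo * w.H1;
  logits.each_col() += net.bo;
  w.P.set_size(2, n);
  for (size_t s = 0; s < n; ++s) {
    T z0 = logits(0, s), z1 = logits(1, s);
    T m = z0 > z1 ? z0 : z1;
    T e0 = std::exp(z0 - m), e1 = std::exp(z1 - m);
    T d = e0 + e1;
    w.P(0, s) = e0 / d; w.P(1, s) = e1 / d;
  }
}

// Batch soft-dice loss on the tumor-class probability and its gradient with
// respect to the two logits. L = 1 - (2*sum(p*g) + eps) / (sum p + sum g + eps).
template <typename T>
static T softdice_and_dlogits(const arma::Mat<T>& P, const arma::Col<T>& g,
                              double eps, arma::Mat<T>& dlogits) {
  const size_t n = P.n_cols;
  double sp = 0, sg = 0, spg = 0;
  for (size_t s = 0; s < n; ++s) {
    sp += (double)P(1, s);
    sg += (double)g[s];
    spg += (double)P(1, s) * (double)g[s];
  }
  const double num = 2.0 * spg + eps, den = sp + sg + eps;
  const double loss = 1.0 - num / den;
  dlogits.set_size(2, n);
  for (size_t s = 0; s < n; ++s) {
    double dLdp1 = -(2.0 * (double)g[s] * den - num) / (den * den);
    double dz1 = dLdp1 * (double)P(1, s) * (double)P(0, s);
    dlogits(1, s) = (T)dz1;
    dlogits(0, s) = (T)(-dz1);
  }
  return (T)loss;
}

// ---------------------------------------------------------------- backward

template <typename T>
static void backward(Net<T>& net, Work<T>& w, Grads<T>& gr) {
  const int F = net.F, D1 = net.D1;
  const size_t n = w.P.n_cols;
  gr.Wo = w.dlogits * w.H1.t();
  gr.bo = arma::sum(w.dlogits, 1);
  w.dH1 = net.Wo.t() * w.dlogits;
  {
    T* d = w.dH1.memptr(); const T* h = w.H1.memptr();
    for (size_t i = 0; i < w.dH1.n_elem; ++i) if (h[i] <= (T)0) d[i] = 0;
  }
  gr.Wh = w.dH1 * w.ZZ.t();
  gr.bh = arma::sum(w.dH1, 1);
  w.dZZ = net.Wh.t() * w.dH1;

  for (int b = 0; b < NBRANCH; ++b) {
    w.dZ = w.dZZ.rows(b * D1, (b + 1) * D1 - 1);
    {
      T* d = w.dZ.memptr(); const T* z = w.Z[b].memptr();
      for (size_t i = 0; i < w.dZ.n_elem; ++i) if (z[i] <= (T)0) d[i] = 0;
    }
    gr.Wd[b] = w.dZ * w.pooled[b].t();
    gr.bd[b] = arma::sum(w.dZ, 1);
    w.dpool = net.Wd[b].t() * w.dZ;              // 256F x n
    if (w.drop[b].n_elem) w.dpool %= w.drop[b];

    // scatter through max pool (gradient only where the pooled value was
    // > 0); pooled units own disjoint 2x2 blocks, so each dY cell is
    // written at most once and the batch-norm sums can be accumulated here
    const int PR = F * (NPIX / 4);
    const size_t N = NPIX * n;
    w.dY.set_size(F, N);
    w.dY.zeros();
    arma::Col<double> sdy(F, arma::fill::zeros), sdyx(F, arma::fill::zeros);
    {
      const T* mup = w.mu[b].memptr();
      const T* isp = w.invstd[b].memptr();
      double* a1 = sdy.memptr(); double* a2 = sdyx.memptr();
      for (size_t s = 0; s < n; ++s) {
        const T* dp = w.dpool.colptr(s);
        const T* pv = w.pooled[b].colptr(s);
        const uint16_t* wn = &w.win[b][(size_t)s * PR];
        for (int f = 0; f < F; ++f) {
          const int base = (NPIX / 4) * f;
          for (int r = 0; r < NPIX / 4; ++r) {
            const T d = dp[base + r];
            if (d == (T)0 || pv[base + r] <= (T)0) continue;
            const size_t col = NPIX * s + wn[base + r];
            w.dY(f, col) = d;
            a1[f] += (double)d;
            a2[f] += (double)d *
                     (double)((w.conv[b](f, col) - mup[f]) * isp[f]);
          }
        }
      }
    }
    gr.gamma[b].set_size(F); gr.beta[b].set_size(F);
    for (int f = 0; f < F; ++f) {
      gr.gamma[b][f] = (T)sdyx[f];
      gr.beta[b][f] = (T)sdy[f];
    }
    // pass 2: dconv = invstd*gamma/N * (N*dY - sum_dY - xhat*sum_dY_xhat),
    // written in place into dY
    {
      T* dy = w.dY.memptr();
      const T* cp = w.conv[b].memptr();
      const T* mup = w.mu[b].memptr();
      const T* isp = w.invstd[b].memptr();
      const T* gam = net.gamma[b].memptr();
      const double Nd = (double)N;
      std::vector<T> k0(F), k1(F), k2(F);
      for (int f = 0; f < F; ++f) {
        const double gi = (double)gam[f] * (double)isp[f] / Nd;
        k0[f] = (T)(gi * Nd);                    // coefficient of dY
        k1[f] = (T)(gi * sdy[f]);                // constant term
        k2[f] = (T)(gi * sdyx[f] * (double)isp[f]); // coefficient of (conv-mu)
      }
      for (size_t c = 0; c < N; ++c, dy += F, cp += F)
        for (int f = 0; f < F; ++f)
          dy[f] = k0[f] * dy[f] - k1[f] - k2[f] * (cp[f] - w.mu[b][f]);
    }
    gr.Wc[b] = w.dY * w.COL[b].t();
  }
}

// ------------------------------------------------------------------- Adam

template <typename T>
struct AdamState {
  std::vector<arma::Mat<T>> m, v;
  long t = 0;
};

template <typename T>
static void grads_collect(Grads<T>& gr, std::vector<arma::Mat<T>*>& gws,
                          std::vector<arma::Col<T>*>& gvs) {
  gws.clear(); gvs.clear();
  for (int b = 0; b < NBRANCH; ++b) {
    gws.push_back(&gr.Wc[b]); gvs.push_back(nullptr);
    gws.push_back(nullptr); gvs.push_back(&gr.gamma[b]);
    gws.push_back(nullptr); gvs.push_back(&gr.beta[b]);
    gws.push_back(&gr.Wd[b]); gvs.push_back(nullptr);
    gws.push_back(nullptr); gvs.push_back(&gr.bd[b]);
  }
  gws.push_back(&gr.Wh); gvs.push_back(nullptr);
  gws.push_back(nullptr); gvs.push_back(&gr.bh);
  gws.push_back(&gr.Wo); gvs.push_back(nullptr);
  gws.push_back(nullptr); gvs.push_back(&gr.bo);
}

template <typename T>
static void adam_step(std::vector<arma::Mat<T>*>& ws,
                      std::vector<arma::Col<T>*>& vs,
                      std::vector<arma::Mat<T>*>& gws,
                      std::vector<arma::Col<T>*>& gvs, AdamState<T>& st,
                      double lr, double b1, double b2, double eps) {
  ++st.t;
  const double c1 = 1.0 - std::pow(b1, (double)st.t);
  const double c2 = 1.0 - std::pow(b2, (double)st.t);
  for (size_t i = 0; i < ws.size(); ++i) {
    const T* g = ws[i] ? gws[i]->memptr() : gvs[i]->memptr();
    const size_t ne = ws[i] ? gws[i]->n_elem : gvs[i]->n_elem;
    if (st.m[i].n_elem == 0) {
      st.m[i].zeros(ne, 1);
      st.v[i].zeros(ne, 1);
    }
    T* mp = st.m[i].memptr(); T* vp = st.v[i].memptr();
    T* wp = ws[i] ? ws[i]->memptr() : vs[i]->memptr();
    const T tb1 = (T)b1, tb2 = (T)b2;
    const T o1 = (T)(1.0 - b1), o2 = (T)(1.0 - b2);
    const T ic1 = (T)(1.0 / c1), ic2 = (T)(1.0 / c2);
    const T tlr = (T)lr, teps = (T)eps;
    for (size_t j = 0; j < ne; ++j) {
      const T gj = g[j];
      mp[j] = tb1 * mp[j] + o1 * gj;
      vp[j] = tb2 * vp[j] + o2 * gj * gj;
      wp[j] -= tlr * (mp[j] * ic1) /
               (std::sqrt(vp[j] * ic2) + teps);
    }
  }
}

// ----------------------------------------------------------- driver helpers

template <typename T>
static std::vector<std::array<arma::Cube<T>, NCH>> cubes_from_r(const List& vols) {
  std::vector<std::array<arma::Cube<T>, NCH>> out(vols.size());
  for (int c = 0; c < vols.size(); ++c) {
    List vl = vols[c];
    if (vl.size() != NCH) stop("each case must supply %d channel volumes", NCH);
    for (int ch = 0; ch < NCH; ++ch) {
      NumericVector a(vl[ch]);
      IntegerVector d = a.attr("dim");
      if (d.size() != 3) stop("channel volumes must be 3D arrays");
      arma::Cube<T>& cube = out[c][ch];
      cube.set_size(d[0], d[1], d[2]);
      const double* src = REAL(a);
      T* dst = cube.memptr();
      for (size_t i = 0; i < cube.n_elem; ++i) dst[i] = (T)src[i];
    }
  }
  return out;
}

template <typename T>
static void patches_from_r(const List& X, std::vector<arma::Mat<T>>& out) {
  if (X.size() != NBRANCH) stop("expected %d patch blocks", NBRANCH);
  for (int b = 0; b < NBRANCH; ++b) {
    out[b] = as_matT<T>(X[b]);
    if ((int)out[b].n_rows != XROWS) stop("patch blocks must have %d rows", XROWS);
  }
}

static double sched_lr(double lr0, double decay, int every, int epoch) {
  return lr0 * std::pow(decay, (double)(epoch / every));
}

static double prof_acc[4] = {0, 0, 0, 0};

// [[Rcpp::export]]
NumericVector cpp_engine_prof() {
  NumericVector out(4);
  for (int i = 0; i < 4; ++i) { out[i] = prof_acc[i]; prof_acc[i] = 0; }
  out.names() = CharacterVector::create("forward", "head", "backward", "adam");
  return out;
}

// One optimization step; expects w.X filled. Returns the batch loss.
template <typename T>
static T train_step(Net<T>& net, Work<T>& w, Grads<T>& gr,
                    const arma::Col<T>& labels, double eps_dice,
                    std::mt19937_64& rng, AdamState<T>& adam, double lr,
                    double b1, double b2, double adam_eps) {
  arma::wall_clock wc;
  wc.tic();
  for (int b = 0; b < NBRANCH; ++b)
    forward_branch(net, b, w, true, &rng, true, true);
  prof_acc[0] += wc.toc(); wc.tic();
  forward_head(net, w);
  T loss = softdice_and_dlogits(w.P, labels, eps_dice, w.dlogits);
  prof_acc[1] += wc.toc(); wc.tic();
  backward(net, w, gr);
  prof_acc[2] += wc.toc(); wc.tic();
  std::vector<arma::Mat<T>*> ws, gws;
  std::vector<arma::Col<T>*> vs, gvs;
  std::vector<std::string> names;
  collect_trainables(net, ws, vs, names);
  grads_collect(gr, gws, gvs);
  adam_step(ws, vs, gws, gvs, adam, lr, b1, b2, adam_eps);
  prof_acc[3] += wc.toc();
  return loss;
}

struct TrainOpt {
  int epochs, batch, every, epoch_offset;
  double lr0, decay, b1, b2, aeps, eps_dice, seed;
  bool shuffle;
};

static TrainOpt opt_from_r(const List& opt) {
  TrainOpt o;
  o.epochs = as<int>(opt["epochs"]);
  o.batch = as<int>(opt["batch_size"]);
  o.lr0 = as<double>(opt["lr0"]);
  o.decay = as<double>(opt["lr_decay"]);
  o.every = as<int>(opt["lr_decay_every"]);
  o.epoch_offset = as<int>(opt["epoch_offset"]);
  o.b1 = as<double>(opt["adam_beta1"]);
  o.b2 = as<double>(opt["adam_beta2"]);
  o.aeps = as<double>(opt["adam_eps"]);
  o.eps_dice = as<double>(opt["dice_eps"]);
  o.seed = as<double>(opt["seed"]);
  o.shuffle = as<bool>(opt["shuffle"]);
  if (o.epochs < 1) stop("epochs must be >= 1");
  if (o.batch < 1) stop("batch size must be >= 1");
  return o;
}

template <typename T>
static AdamState<T> adam_from_r(SEXP adam_in, size_t ntens) {
  AdamState<T> st;
  st.m.resize(ntens);
  st.v.resize(ntens);
  if (!Rf_isNull(adam_in)) {
    List al(adam_in);
    List m = al["m"], v = al["v"];
    st.t = (long)as<double>(al["t"]);
    for (size_t i = 0; i < ntens; ++i) {
      st.m[i] = as_matT<T>(m[i]);
      st.v[i] = as_matT<T>(v[i]);
    }
  }
  return st;
}

template <typename T>
static List adam_to_r(const AdamState<T>& st) {
  List m(st.m.size()), v(st.v.size());
  for (size_t i = 0; i < st.m.size(); ++i) {
    m[i] = to_rmat(st.m[i]);
    v[i] = to_rmat(st.v[i]);
  }
  return List::create(_["m"] = m, _["v"] = v, _["t"] = (double)st.t);
}

// ------------------------------------------------------------------ exports

// Train on sampled voxels of padded standard-space cases.
// vols: list over cases of list(T1, T1gad, STIR) padded arrays.
// samples: n x 5 integer matrix (case 0-based, i, j, k 0-based unpadded, label).
// [[Rcpp::export]]
List cpp_mvcnn_train(List vols, IntegerMatrix samples, List params, List cfg,
                     List opt, SEXP adam_in) {
  typedef float T;
  Net<T> net = net_from_r<T>(params, cfg);
  auto cubes = cubes_from_r<T>(vols);
  arma::imat samp(samples.nrow(), samples.ncol());
  for (int i = 0; i < samples.nrow(); ++i)
    for (int j = 0; j < samples.ncol(); ++j) samp(i, j) = samples(i, j);
  const int nsamp = samples.nrow();
  if (nsamp < 1) stop("no training samples");
  TrainOpt o = opt_from_r(opt);

  std::mt19937_64 rng((uint64_t)o.seed);
  std::vector<arma::Mat<T>*> ws;
  std::vector<arma::Col<T>*> vs;
  std::vector<std::string> names;
  collect_trainables(net, ws, vs, names);
  AdamState<T> adam = adam_from_r<T>(adam_in, ws.size());

  std::vector<arma::uword> order(nsamp);
  for (int i = 0; i < nsamp; ++i) order[i] = i;
  NumericVector history(o.epochs);
  Work<T> w;
  Grads<T> gr;

  for (int ep = 0; ep < o.epochs; ++ep) {
    const double lr = sched_lr(o.lr0, o.decay, o.every, ep + o.epoch_offset);
    if (o.shuffle) std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int nb = 0;
    for (int start = 0; start < nsamp; start += o.batch) {
      const int bn = std::min(o.batch, nsamp - start);
      arma::uvec idx(bn);
      arma::Col<T> labels(bn);
      for (int s = 0; s < bn; ++s) {
        idx[s] = order[start + s];
        labels[s] = (T)samp(idx[s], 4);
      }
      build_patch_blocks(cubes, samp, idx, w.X);
      loss_sum += (double)train_step(net, w, gr, labels, o.eps_dice, rng,
                                     adam, lr, o.b1, o.b2, o.aeps);
      ++nb;
      Rcpp::checkUserInterrupt();
    }
    history[ep] = loss_sum / std::max(nb, 1);
  }
  return List::create(_["params"] = net_to_r(net), _["adam"] = adam_to_r(adam),
                      _["history"] = history);
}

// Train directly on fixed patch blocks (used by small-scale tests).
// [[Rcpp::export]]
List cpp_mvcnn_train_patches(List X_in, NumericVector labels_in, List params,
                             List cfg, List opt, SEXP adam_in) {
  typedef float T;
  Net<T> net = net_from_r<T>(params, cfg);
  std::vector<arma::Mat<T>> X0(NBRANCH);
  patches_from_r<T>(X_in, X0);
  const int nsamp = (int)X0[0].n_cols;
  arma::Col<T> labels(nsamp);
  for (int i = 0; i < nsamp; ++i) labels[i] = (T)labels_in[i];
  TrainOpt o = opt_from_r(opt);

  std::mt19937_64 rng((uint64_t)o.seed);
  std::vector<arma::Mat<T>*> ws;
  std::vector<arma::Col<T>*> vs;
  std::vector<std::string> names;
  collect_trainables(net, ws, vs, names);
  AdamState<T> adam = adam_from_r<T>(adam_in, ws.size());

  std::vector<arma::uword> order(nsamp);
  for (int i = 0; i < nsamp; ++i) order[i] = i;
  NumericVector history(o.epochs);
  Work<T> w;
  Grads<T> gr;
  for (int ep = 0; ep < o.epochs; ++ep) {
    const double lr = sched_lr(o.lr0, o.decay, o.every, ep + o.epoch_offset);
    if (o.shuffle) std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int nb = 0;
    for (int start = 0; start < nsamp; start += o.batch) {
      const int bn = std::min(o.batch, nsamp - start);
      arma::Col<T> lb(bn);
      for (int b = 0; b < NBRANCH; ++b) w.X[b].set_size(XROWS, bn);
      for (int s = 0; s < bn; ++s) {
        lb[s] = labels[order[start + s]];
        for (int b = 0; b < NBRANCH; ++b)
          w.X[b].col(s) = X0[b].col(order[start + s]);
      }
      loss_sum += (double)train_step(net, w, gr, lb, o.eps_dice, rng, adam,
                                     lr, o.b1, o.b2, o.aeps);
      ++nb;
    }
    history[ep] = loss_sum / std::max(nb, 1);
  }
  return List::create(_["params"] = net_to_r(net), _["adam"] = adam_to_r(adam),
                      _["history"] = history);
}

// Class probabilities for explicit patch blocks. training = TRUE uses batch
// statistics and (seeded) dropout, as during optimization.
// [[Rcpp::export]]
NumericMatrix cpp_mvcnn_forward_patches(List X_in, List params, List cfg,
                                        bool training, double seed) {
  typedef double T;   // forward-only path is cheap; double keeps tests strict
  Net<T> net = net_from_r<T>(params, cfg);
  Work<T> w;
  std::vector<arma::Mat<T>> X0(NBRANCH);
  patches_from_r<T>(X_in, X0);
  for (int b = 0; b < NBRANCH; ++b) w.X[b] = X0[b];
  std::mt19937_64 rng((uint64_t)seed);
  for (int b = 0; b < NBRANCH; ++b)
    forward_branch(net, b, w, training, training ? &rng : nullptr, false,
                   false);
  forward_head(net, w);
  return to_rmat(arma::mat(w.P));
}

// Tumor-class probability for a set of voxels of one padded case.
// [[Rcpp::export]]
NumericVector cpp_mvcnn_predict(List vols_one, IntegerMatrix voxels,
                                List params, List cfg, int batch) {
  typedef float T;
  Net<T> net = net_from_r<T>(params, cfg);
  List wrap = List::create(vols_one);
  auto cubes = cubes_from_r<T>(wrap);
  const int n = voxels.nrow();
  arma::imat samp(n, 5);
  for (int i = 0; i < n; ++i) {
    samp(i, 0) = 0;
    for (int j = 0; j < 3; ++j) samp(i, j + 1) = voxels(i, j);
    samp(i, 4) = 0;
  }
  NumericVector out(n);
  Work<T> w;
  for (int start = 0; start < n; start += batch) {
    const int bn = std::min(batch, n - start);
    arma::uvec idx(bn);
    for (int s = 0; s < bn; ++s) idx[s] = start + s;
    build_patch_blocks(cubes, samp, idx, w.X);
    for (int b = 0; b < NBRANCH; ++b)
      forward_branch(net, b, w, false, nullptr, false, false);
    forward_head(net, w);
    for (int s = 0; s < bn; ++s) out[start + s] = (double)w.P(1, s);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Loss and exact gradients in double precision on fixed patch blocks, with
// batch-statistics batch norm and no dropout: the target of the
// finite-difference gradient test.
// [[Rcpp::export]]
List cpp_mvcnn_loss_grad(List X_in, NumericVector labels_in, List params,
                         List cfg, double eps_dice) {
  typedef double T;
  Net<T> net = net_from_r<T>(params, cfg);
  net.drop = 0;
  Work<T> w;
  std::vector<arma::Mat<T>> X0(NBRANCH);
  patches_from_r<T>(X_in, X0);
  for (int b = 0; b < NBRANCH; ++b) w.X[b] = X0[b];
  const int n = (int)w.X[0].n_cols;
  arma::Col<T> labels(n);
  for (int i = 0; i < n; ++i) labels[i] = labels_in[i];
  for (int b = 0; b < NBRANCH; ++b)
    forward_branch(net, b, w, true, nullptr, true, false);
  forward_head(net, w);
  T loss = softdice_and_dlogits(w.P, labels, eps_dice, w.dlogits);
  Grads<T> gr;
  backward(net, w, gr);

  std::vector<arma::Mat<T>*> gws;
  std::vector<arma::Col<T>*> gvs;
  grads_collect(gr, gws, gvs);
  std::vector<arma::Mat<T>*> ws;
  std::vector<arma::Col<T>*> vs;
  std::vector<std::string> names;
  collect_trainables(net, ws, vs, names);
  List grads;
  for (size_t i = 0; i < names.size(); ++i)
    grads[names[i]] = gws[i] ? to_rmat(*gws[i]) : to_rmat(arma::Mat<T>(*gvs[i]));
  return List::create(_["loss"] = (double)loss, _["grads"] = grads);
}

// Extract the six tri-planar pyramid patches around one voxel of a padded
// case; returns 32x32x3 arrays in branch order
// (axial s0, axial s1, coronal s0, coronal s1, sagittal s0, sagittal s1).
// [[Rcpp::export]]
List cpp_extract_patchset(List vols_one, int i, int j, int k) {
  typedef double T;
  List wrap = List::create(vols_one);
  auto cubes = cubes_from_r<T>(wrap);
  List out(NBRANCH);
  const int ci = i + PAD, cj = j + PAD, ck = k + PAD;
  for (int view = 0; view < 3; ++view)
    for (int scale = 0; scale < 2; ++scale) {
      const int b = view * 2 + scale;
      NumericVector arr((R_xlen_t)XROWS);
      std::vector<T> buf(XROWS);
      for (int ch = 0; ch < NCH; ++ch)
        fill_patch(cubes[0][ch], ci, cj, ck, view, scale, buf.data() + NPIX * ch);
      std::copy(buf.begin(), buf.end(), arr.begin());
      arr.attr("dim") = IntegerVector::create(PATCH, PATCH, NCH);
      out[b] = arr;
    }
  return out;
}
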