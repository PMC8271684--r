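// Compact U-Net engine: batch-normalised 3x3 conv blocks with leaky-ReLU
// activations, 2x2 max-pooling encoder, decoder with either nearest-neighbour
// up-sampling or 2x2 up-convolution (both followed by skip concatenation),
// and a 1x1 sigmoid head. Training uses pixel-wise binary cross-entropy and
// Adam. Single precision throughout; all randomness is drawn from R's RNG so
// set.seed() fully determines initialisation, shuffling and augmentation.
//
// Feature maps are stored as (N*H*W) x C matrices; within a sample, pixels
// are column-major (row index fastest), matching R's matrix layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

struct ConvDef {
  int kind;   // 0 = 3x3 same conv, 1 = 1x1 head conv, 2 = 2x2 stride-2 up-conv
  int cin, cout;
  bool bn;
  int woff;   // offset into flat weight vector
  int soff;   // offset into flat moving-statistics vector (-1 if no BN)
};

struct Net {
  int base, depth, inch, H, W;
  bool bn;
  float slope;
  bool tconv;               // true: up-convolution decoder, false: upsample
  std::vector<int> f;       // filters per resolution level
  std::vector<ConvDef> convs;
  int nW = 0, nS = 0;
};

static int k2_of(int kind) { return kind == 0 ? 9 : (kind == 1 ? 1 : 4); }

static void add_conv(Net& n, int kind, int cin, int cout, bool bn) {
  ConvDef c;
  c.kind = kind; c.cin = cin; c.cout = cout; c.bn = bn;
  c.woff = n.nW;
  n.nW += k2_of(kind) * cin * cout + cout + (bn ? 2 * cout : 0);
  c.soff = bn ? n.nS : -1;
  if (bn) n.nS += 2 * cout;
  n.convs.push_back(c);
}

static Net make_net(List spec) {
  Net n;
  n.base  = as<int>(spec["base"]);
  n.depth = as<int>(spec["depth"]);
  n.inch  = as<int>(spec["inch"]);
  n.H     = as<int>(spec["H"]);
  n.W     = as<int>(spec["W"]);
  n.bn    = as<bool>(spec["bn"]);
  n.slope = (float)as<double>(spec["slope"]);
  std::string dm = as<std::string>(spec["decoder"]);
  n.tconv = (dm == "upconv_concat");
  n.f.resize(n.depth);
  for (int i = 0; i < n.depth; ++i) n.f[i] = n.base << i;
  int prev = n.inch;
  for (int l = 0; l < n.depth - 1; ++l) {           // encoder blocks
    add_conv(n, 0, prev, n.f[l], n.bn);
    add_conv(n, 0, n.f[l], n.f[l], n.bn);
    prev = n.f[l];
  }
  add_conv(n, 0, prev, n.f[n.depth - 1], n.bn);     // bottleneck block
  add_conv(n, 0, n.f[n.depth - 1], n.f[n.depth - 1], n.bn);
  prev = n.f[n.depth - 1];
  for (int l = n.depth - 2; l >= 0; --l) {          // decoder blocks
    int cat;
    if (n.tconv) { add_conv(n, 2, prev, n.f[l], n.bn); cat = 2 * n.f[l]; }
    else         { cat = prev + n.f[l]; }
    add_conv(n, 0, cat, n.f[l], n.bn);
    add_conv(n, 0, n.f[l], n.f[l], n.bn);
    prev = n.f[l];
  }
  add_conv(n, 1, prev, 1, false);                   // sigmoid head (logits)
  return n;
}

// ---- primitive ops ---------------------------------------------------------

// out column c*9+o holds channel c shifted by offset o=(di+1)*3+(dj+1)
static void im2col3(const fmat& X, int N, int H, int W, fmat& out) {
  const int HW = H * W, C = X.n_cols;
  out.zeros(X.n_rows, 9 * (uword)C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    for (int di = -1; di <= 1; ++di) for (int dj = -1; dj <= 1; ++dj) {
      int o = (di + 1) * 3 + (dj + 1);
      float* op = out.colptr((uword)c * 9 + o);
      int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
      int len = i1 - i0 + 1;
      if (len <= 0) continue;
      for (int nn = 0; nn < N; ++nn) {
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          const float* src = xp + (size_t)nn * HW + (size_t)js * H + (i0 + di);
          float* dst = op + (size_t)nn * HW + (size_t)j * H + i0;
          memcpy(dst, src, len * sizeof(float));
        }
      }
    }
  }
}

static void col2im3(const fmat& G, int N, int H, int W, int C, fmat& dX) {
  const int HW = H * W;
  dX.zeros((uword)N * HW, C);
  for (int c = 0; c < C; ++c) {
    float* dp = dX.colptr(c);
    for (int di = -1; di <= 1; ++di) for (int dj = -1; dj <= 1; ++dj) {
      int o = (di + 1) * 3 + (dj + 1);
      const float* gp = G.colptr((uword)c * 9 + o);
      int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
      int len = i1 - i0 + 1;
      if (len <= 0) continue;
      for (int nn = 0; nn < N; ++nn) {
        for (int j = 0; j < W; ++j) {
          int js = j + dj;
          if (js < 0 || js >= W) continue;
          const float* g = gp + (size_t)nn * HW + (size_t)j * H + i0;
          float* d = dp + (size_t)nn * HW + (size_t)js * H + (i0 + di);
          for (int t = 0; t < len; ++t) d[t] += g[t];
        }
      }
    }
  }
}

static void maxpool(const fmat& X, int N, int H, int W, fmat& Y, arma::umat& idx) {
  int C = X.n_cols, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  Y.set_size((uword)N * HW2, C);
  idx.set_size((uword)N * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    uword* ip = idx.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          size_t r00 = (size_t)nn * HW + (size_t)(2 * j) * H + 2 * i;
          size_t r01 = r00 + H;
          size_t rb = r00; float v = xp[r00];
          if (xp[r00 + 1] > v) { v = xp[r00 + 1]; rb = r00 + 1; }
          if (xp[r01] > v)     { v = xp[r01];     rb = r01; }
          if (xp[r01 + 1] > v) { v = xp[r01 + 1]; rb = r01 + 1; }
          size_t out = (size_t)nn * HW2 + (size_t)j * H2 + i;
          yp[out] = v; ip[out] = rb;
        }
  }
}

static void maxpool_bwd(const fmat& dY, const arma::umat& idx, uword rowsX, fmat& dX) {
  dX.zeros(rowsX, dY.n_cols);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* gp = dY.colptr(c);
    const uword* ip = idx.colptr(c);
    float* dp = dX.colptr(c);
    for (uword r = 0; r < dY.n_rows; ++r) dp[ip[r]] += gp[r];
  }
}

static void upsample2(const fmat& X, int N, int H, int W, fmat& Y) {
  int C = X.n_cols, H2 = 2 * H, W2 = 2 * W, HW = H * W, HW2 = H2 * W2;
  Y.set_size((uword)N * HW2, C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      for (int j = 0; j < W2; ++j) {
        const float* src = xp + (size_t)nn * HW + (size_t)(j / 2) * H;
        float* dst = yp + (size_t)nn * HW2 + (size_t)j * H2;
        for (int i = 0; i < H2; ++i) dst[i] = src[i / 2];
      }
  }
}

static void upsample2_bwd(const fmat& dY, int N, int H, int W, fmat& dX) {
  int C = dY.n_cols, H2 = 2 * H, W2 = 2 * W, HW = H * W, HW2 = H2 * W2;
  dX.zeros((uword)N * HW, C);
  for (int c = 0; c < C; ++c) {
    const float* gp = dY.colptr(c);
    float* dp = dX.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      for (int j = 0; j < W2; ++j) {
        float* d = dp + (size_t)nn * HW + (size_t)(j / 2) * H;
        const float* g = gp + (size_t)nn * HW2 + (size_t)j * H2;
        for (int i = 0; i < H2; ++i) d[i / 2] += g[i];
      }
  }
}

// scatter GEMM result for one 2x2 offset into the doubled grid
static void tconv_scatter(const fmat& Yo, int N, int H, int W, int di, int dj, fmat& Y) {
  int C = Yo.n_cols, HW = H * W, H2 = 2 * H, HW2 = 4 * HW;
  for (int c = 0; c < C; ++c) {
    const float* sp = Yo.colptr(c);
    float* yp = Y.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      for (int j = 0; j < W; ++j) {
        const float* s = sp + (size_t)nn * HW + (size_t)j * H;
        float* d = yp + (size_t)nn * HW2 + (size_t)(2 * j + dj) * H2 + di;
        for (int i = 0; i < H; ++i) d[2 * i] = s[i];
      }
  }
}

static void tconv_gather(const fmat& dY, int N, int H, int W, int di, int dj, fmat& Go) {
  int C = dY.n_cols, HW = H * W, H2 = 2 * H, HW2 = 4 * HW;
  Go.set_size((uword)N * HW, C);
  for (int c = 0; c < C; ++c) {
    float* gp = Go.colptr(c);
    const float* yp = dY.colptr(c);
    for (int nn = 0; nn < N; ++nn)
      for (int j = 0; j < W; ++j) {
        float* g = gp + (size_t)nn * HW + (size_t)j * H;
        const float* y = yp + (size_t)nn * HW2 + (size_t)(2 * j + dj) * H2 + di;
        for (int i = 0; i < H; ++i) g[i] = y[2 * i];
      }
  }
}

// ---- batch normalisation ---------------------------------------------------

static const float BN_EPS = 1e-3f;
static const float BN_MOMENTUM = 0.99f;

struct BNCache { fmat xhat; frowvec invstd; };

static void bn_forward(fmat& Y, const float* gamma, const float* beta,
                       float* smean, float* svar, bool training, BNCache* C) {
  int Cc = Y.n_cols;
  if (training) {
    frowvec mu = arma::mean(Y, 0);
    fmat cent = Y;
    cent.each_row() -= mu;
    frowvec var = arma::mean(arma::square(cent), 0);
    frowvec inv = 1.0f / arma::sqrt(var + BN_EPS);
    cent.each_row() %= inv;                       // xhat
    for (int c = 0; c < Cc; ++c) {
      smean[c] = BN_MOMENTUM * smean[c] + (1 - BN_MOMENTUM) * mu[c];
      svar[c]  = BN_MOMENTUM * svar[c]  + (1 - BN_MOMENTUM) * var[c];
      Y.col(c) = cent.col(c) * gamma[c] + beta[c];
    }
    if (C) { C->xhat = std::move(cent); C->invstd = inv; }
  } else {
    for (int c = 0; c < Cc; ++c) {
      float inv = 1.0f / std::sqrt(svar[c] + BN_EPS);
      Y.col(c) = (Y.col(c) - smean[c]) * (inv * gamma[c]) + beta[c];
    }
  }
}

static void bn_backward(const fmat& dY, const BNCache& C, const float* gamma,
                        fmat& dX, float* dgamma, float* dbeta) {
  int Cc = dY.n_cols;
  double N = dY.n_rows;
  dX.set_size(dY.n_rows, Cc);
  for (int c = 0; c < Cc; ++c) {
    const fvec dy = dY.col(c);
    const fvec xh = C.xhat.col(c);
    double sdy = arma::accu(dy), sdyx = arma::dot(dy, xh);
    dgamma[c] += (float)sdyx;
    dbeta[c]  += (float)sdy;
    dX.col(c) = (gamma[c] * C.invstd[c]) *
                (dy - (float)(sdy / N) - xh * (float)(sdyx / N));
  }
}

// ---- forward / backward ----------------------------------------------------

struct FwdCache {
  std::vector<fmat> cin;          // input of each conv
  std::vector<BNCache> bnc;
  std::vector<fmat> aout;         // activated output of each conv
  std::vector<int> Hin, Win;      // input grid of each conv
  std::vector<arma::umat> pidx;   // max-pool argmax per encoder level
  FwdCache(size_t nconv, int nlev)
      : cin(nconv), bnc(nconv), aout(nconv), Hin(nconv, 0), Win(nconv, 0),
        pidx(nlev) {}
};

static fmat apply_conv(const Net& net, const fvec& Wt, fvec& St, int k,
                       const fmat& X, int N, int Hc, int Wc, bool training,
                       FwdCache* C) {
  const ConvDef& cd = net.convs[k];
  const float* wp = Wt.memptr() + cd.woff;
  int kk = k2_of(cd.kind);
  fmat Y;
  if (cd.kind == 0) {
    fmat cols;
    im2col3(X, N, Hc, Wc, cols);
    const fmat Wm(const_cast<float*>(wp), 9 * cd.cin, cd.cout, false, true);
    Y = cols * Wm;
  } else if (cd.kind == 1) {
    const fmat Wm(const_cast<float*>(wp), cd.cin, cd.cout, false, true);
    Y = X * Wm;
  } else {
    Y.zeros((uword)N * 4 * Hc * Wc, cd.cout);
    for (int o = 0; o < 4; ++o) {
      const fmat Wo(const_cast<float*>(wp + (size_t)o * cd.cin * cd.cout),
                    cd.cin, cd.cout, false, true);
      fmat Yo = X * Wo;
      tconv_scatter(Yo, N, Hc, Wc, o / 2, o % 2, Y);
    }
  }
  const float* bp = wp + (size_t)kk * cd.cin * cd.cout;
  for (int c = 0; c < cd.cout; ++c) Y.col(c) += bp[c];
  if (C) { C->cin[k] = X; C->Hin[k] = Hc; C->Win[k] = Wc; }
  if (cd.bn) {
    const float* g = bp + cd.cout;
    const float* be = g + cd.cout;
    bn_forward(Y, g, be, St.memptr() + cd.soff, St.memptr() + cd.soff + cd.cout,
               training, C ? &C->bnc[k] : nullptr);
  }
  if (cd.kind != 1) Y = arma::max(Y, net.slope * Y);
  if (C) C->aout[k] = Y;
  return Y;
}

static fmat unet_forward(const Net& net, const fvec& Wt, fvec& St, const fmat& X0,
                         int N, bool training, FwdCache* C) {
  int d = net.depth;
  std::vector<fmat> skip(d - 1);
  fmat cur = X0;
  int k = 0;
  for (int l = 0; l < d - 1; ++l) {
    int Hc = net.H >> l, Wc = net.W >> l;
    cur = apply_conv(net, Wt, St, k++, cur, N, Hc, Wc, training, C);
    cur = apply_conv(net, Wt, St, k++, cur, N, Hc, Wc, training, C);
    skip[l] = cur;
    fmat pooled;
    arma::umat pi;
    maxpool(cur, N, Hc, Wc, pooled, pi);
    if (C) C->pidx[l] = std::move(pi);
    cur = pooled;
  }
  {
    int l = d - 1, Hc = net.H >> l, Wc = net.W >> l;
    cur = apply_conv(net, Wt, St, k++, cur, N, Hc, Wc, training, C);
    cur = apply_conv(net, Wt, St, k++, cur, N, Hc, Wc, training, C);
  }
  for (int l = d - 2; l >= 0; --l) {
    int Hc = net.H >> (l + 1), Wc = net.W >> (l + 1);
    fmat up;
    if (net.tconv) up = apply_conv(net, Wt, St, k++, cur, N, Hc, Wc, training, C);
    else upsample2(cur, N, Hc, Wc, up);
    fmat cat = arma::join_rows(up, skip[l]);
    int Ho = net.H >> l, Wo = net.W >> l;
    cur = apply_conv(net, Wt, St, k++, cat, N, Ho, Wo, training, C);
    cur = apply_conv(net, Wt, St, k++, cur, N, Ho, Wo, training, C);
  }
  return apply_conv(net, Wt, St, k++, cur, N, net.H, net.W, training, C);
}

// backward through conv k given gradient at its (activated) output
static fmat conv_bwd(const Net& net, const fvec& Wt, const FwdCache& C, int k,
                     const fmat& dA, int N, fvec& G) {
  const ConvDef& cd = net.convs[k];
  const float* wp = Wt.memptr() + cd.woff;
  int kk = k2_of(cd.kind);
  float* gw = G.memptr() + cd.woff;
  float* gb = gw + (size_t)kk * cd.cin * cd.cout;
  fmat dLin;
  if (cd.kind == 1) {
    dLin = dA;
  } else {
    // leaky-ReLU backward: slope branch where the activation is non-positive
    fmat dAct = dA;
    const fmat& A = C.aout[k];
    float sl = net.slope;
    for (uword c = 0; c < dAct.n_cols; ++c) {
      float* dp = dAct.colptr(c);
      const float* ap = A.colptr(c);
      for (uword r = 0; r < dAct.n_rows; ++r)
        if (ap[r] <= 0) dp[r] *= sl;
    }
    if (cd.bn) {
      const float* gamma = wp + (size_t)kk * cd.cin * cd.cout + cd.cout;
      float* dgamma = gb + cd.cout;
      float* dbeta = dgamma + cd.cout;
      bn_backward(dAct, C.bnc[k], gamma, dLin, dgamma, dbeta);
    } else {
      dLin = std::move(dAct);
    }
  }
  for (int c = 0; c < cd.cout; ++c) gb[c] += arma::accu(dLin.col(c));
  int Hc = C.Hin[k], Wc = C.Win[k];
  fmat dX;
  if (cd.kind == 0) {
    fmat cols;
    im2col3(C.cin[k], N, Hc, Wc, cols);
    fmat Gw(gw, 9 * cd.cin, cd.cout, false, true);
    Gw += cols.t() * dLin;
    const fmat Wm(const_cast<float*>(wp), 9 * cd.cin, cd.cout, false, true);
    fmat dcols = dLin * Wm.t();
    col2im3(dcols, N, Hc, Wc, cd.cin, dX);
  } else if (cd.kind == 1) {
    fmat Gw(gw, cd.cin, cd.cout, false, true);
    Gw += C.cin[k].t() * dLin;
    const fmat Wm(const_cast<float*>(wp), cd.cin, cd.cout, false, true);
    dX = dLin * Wm.t();
  } else {
    dX.zeros((uword)N * Hc * Wc, cd.cin);
    for (int o = 0; o < 4; ++o) {
      fmat dYo;
      tconv_gather(dLin, N, Hc, Wc, o / 2, o % 2, dYo);
      fmat Gw(gw + (size_t)o * cd.cin * cd.cout, cd.cin, cd.cout, false, true);
      Gw += C.cin[k].t() * dYo;
      const fmat Wo(const_cast<float*>(wp + (size_t)o * cd.cin * cd.cout),
                    cd.cin, cd.cout, false, true);
      dX += dYo * Wo.t();
    }
  }
  return dX;
}

static void unet_backward(const Net& net, const fvec& Wt, const FwdCache& C,
                          const fmat& dlogits, int N, fvec& G) {
  int d = net.depth;
  int k = (int)net.convs.size() - 1;
  fmat dcur = conv_bwd(net, Wt, C, k--, dlogits, N, G);
  std::vector<fmat> dskip(d - 1);
  for (int l = 0; l <= d - 2; ++l) {            // decoder levels, shallow first
    dcur = conv_bwd(net, Wt, C, k--, dcur, N, G);
    dcur = conv_bwd(net, Wt, C, k--, dcur, N, G);
    int up_ch = net.tconv ? net.f[l] : net.f[l + 1];
    fmat dup = dcur.cols(0, up_ch - 1);
    dskip[l] = dcur.cols(up_ch, up_ch + net.f[l] - 1);
    if (net.tconv) {
      dcur = conv_bwd(net, Wt, C, k--, dup, N, G);
    } else {
      fmat dprev;
      upsample2_bwd(dup, N, net.H >> (l + 1), net.W >> (l + 1), dprev);
      dcur = std::move(dprev);
    }
  }
  dcur = conv_bwd(net, Wt, C, k--, dcur, N, G);  // bottleneck
  dcur = conv_bwd(net, Wt, C, k--, dcur, N, G);
  for (int l = d - 2; l >= 0; --l) {
    uword rowsX = (uword)N * (net.H >> l) * (net.W >> l);
    fmat dpool;
    maxpool_bwd(dcur, C.pidx[l], rowsX, dpool);
    dpool += dskip[l];
    dcur = conv_bwd(net, Wt, C, k--, dpool, N, G);
    dcur = conv_bwd(net, Wt, C, k--, dcur, N, G);
  }
}

// ---- loss ------------------------------------------------------------------

static double bce_from_logits(const fmat& z, const fmat& y, fmat& dz,
                              double* acc) {
  double loss = 0;
  uword n = z.n_elem;
  dz.set_size(z.n_rows, z.n_cols);
  const float* zp = z.memptr();
  const float* yp = y.memptr();
  float* dp = dz.memptr();
  uword correct = 0;
  for (uword i = 0; i < n; ++i) {
    double zi = zp[i], yi = yp[i];
    loss += std::max(zi, 0.0) - zi * yi + std::log1p(std::exp(-std::fabs(zi)));
    double p = 1.0 / (1.0 + std::exp(-zi));
    dp[i] = (float)((p - yi) / n);
    if ((p > 0.5) == (yi > 0.5)) ++correct;
  }
  if (acc) *acc = (double)correct / n;
  return loss / n;
}

// ---- geometric warp (shared by augmentation and augmentPair) ---------------

static void warp_one(const float* src, int H, int W, bool fH, bool fV,
                     double ang, double tx, double ty, double zoom,
                     bool nearest, float* dst) {
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  double th = ang * M_PI / 180.0, c = std::cos(th), s = std::sin(th);
  for (int j = 0; j < W; ++j) {
    double xo = j - cx;
    for (int i = 0; i < H; ++i) {
      double yo = i - cy;
      double xs = (c * (xo - tx) + s * (yo - ty)) / zoom;
      double ys = (-s * (xo - tx) + c * (yo - ty)) / zoom;
      if (fH) xs = -xs;
      if (fV) ys = -ys;
      double X = xs + cx, Y = ys + cy;
      float v = 0.f;
      if (nearest) {
        long ri = std::lround(Y), rj = std::lround(X);
        if (ri >= 0 && ri < H && rj >= 0 && rj < W)
          v = src[ri + (long)H * rj];
      } else {
        int i0 = (int)std::floor(Y), j0 = (int)std::floor(X);
        double dy = Y - i0, dx = X - j0;
        for (int a = 0; a < 2; ++a)
          for (int b = 0; b < 2; ++b) {
            int ii = i0 + a, jj = j0 + b;
            if (ii >= 0 && ii < H && jj >= 0 && jj < W)
              v += (float)(((a ? dy : 1 - dy) * (b ? dx : 1 - dx)) *
                           src[ii + (long)H * jj]);
          }
      }
      dst[i + (long)H * j] = v;
    }
  }
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_init(List spec) {
  Net net = make_net(spec);
  NumericVector w(net.nW), s(net.nS);
  for (const ConvDef& cd : net.convs) {
    int kk = k2_of(cd.kind);
    double sd = std::sqrt(2.0 / (kk * cd.cin));    // He initialisation
    size_t nw = (size_t)kk * cd.cin * cd.cout;
    for (size_t i = 0; i < nw; ++i) w[cd.woff + i] = norm_rand() * sd;
    // biases start at zero, except the sigmoid head whose bias is set to
    // the logit of a 10% foreground prior: the segmented structures cover
    // a small image fraction, and starting from an under-segmenting state
    // stabilises and speeds up cross-entropy training on imbalanced masks
    double b0 = (cd.kind == 1) ? std::log(0.1 / 0.9) : 0.0;
    for (int c = 0; c < cd.cout; ++c) w[cd.woff + nw + c] = b0;
    if (cd.bn) {
      for (int c = 0; c < cd.cout; ++c) {
        w[cd.woff + nw + cd.cout + c] = 1.0;            // gamma
        w[cd.woff + nw + 2 * cd.cout + c] = 0.0;        // beta
        s[cd.soff + c] = 0.0;                           // moving mean
        s[cd.soff + cd.cout + c] = 1.0;                 // moving variance
      }
    }
  }
  return List::create(_["weights"] = w, _["stats"] = s,
                      _["n_trainable"] = net.nW, _["n_stats"] = net.nS);
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(NumericVector weights, NumericVector stats,
                               List spec, NumericMatrix image) {
  Net net = make_net(spec);
  if ((int)weights.size() != net.nW) stop("weight vector has wrong length");
  if ((int)image.nrow() != net.H || (int)image.ncol() != net.W)
    stop("image does not match the network input size");
  fvec Wt(weights.size()), St(std::max((R_xlen_t)1, stats.size()));
  for (R_xlen_t i = 0; i < weights.size(); ++i) Wt[i] = (float)weights[i];
  for (R_xlen_t i = 0; i < stats.size(); ++i) St[i] = (float)stats[i];
  fmat X0((uword)net.H * net.W, net.inch);
  for (int i = 0; i < net.H * net.W; ++i) X0[i] = (float)image[i];
  fmat z = unet_forward(net, Wt, St, X0, 1, false, nullptr);
  NumericMatrix out(net.H, net.W);
  for (int i = 0; i < net.H * net.W; ++i)
    out[i] = 1.0 / (1.0 + std::exp(-(double)z[i]));
  return out;
}

// [[Rcpp::export]]
List cpp_unet_lossgrad(NumericVector weights, NumericVector stats, List spec,
                       NumericVector x, NumericVector y, int nbatch) {
  Net net = make_net(spec);
  if ((int)weights.size() != net.nW) stop("weight vector has wrong length");
  fvec Wt(weights.size()), St(std::max((R_xlen_t)1, stats.size()));
  for (R_xlen_t i = 0; i < weights.size(); ++i) Wt[i] = (float)weights[i];
  for (R_xlen_t i = 0; i < stats.size(); ++i) St[i] = (float)stats[i];
  uword HW = (uword)net.H * net.W;
  fmat X0(HW * nbatch, net.inch), Y0(HW * nbatch, 1);
  for (uword i = 0; i < HW * nbatch; ++i) { X0[i] = (float)x[i]; Y0[i] = (float)y[i]; }
  FwdCache C(net.convs.size(), net.depth - 1);
  fmat z = unet_forward(net, Wt, St, X0, nbatch, true, &C);
  fmat dz;
  double loss = bce_from_logits(z, Y0, dz, nullptr);
  fvec G(net.nW, arma::fill::zeros);
  unet_backward(net, Wt, C, dz, nbatch, G);
  NumericVector g(net.nW);
  for (int i = 0; i < net.nW; ++i) g[i] = (double)G[i];
  return List::create(_["loss"] = loss, _["grad"] = g);
}

// [[Rcpp::export]]
List cpp_unet_train(NumericVector weights, NumericVector stats, List spec,
                    NumericVector images, NumericVector masks, int nimg,
                    int epochs, int batch, double lr,
                    bool augment, List augspec, bool verbose) {
  Net net = make_net(spec);
  if ((int)weights.size() != net.nW) stop("weight vector has wrong length");
  uword HW = (uword)net.H * net.W;
  if ((uword)images.size() != HW * nimg || (uword)masks.size() != HW * nimg)
    stop("image/mask arrays do not match the network input size");
  fvec Wt(weights.size()), St(std::max((R_xlen_t)1, stats.size()));
  for (R_xlen_t i = 0; i < weights.size(); ++i) Wt[i] = (float)weights[i];
  for (R_xlen_t i = 0; i < stats.size(); ++i) St[i] = (float)stats[i];

  double p_fh = 0.5, p_fv = 0.5, rot_max = 360.0, trans_max = 70.0;
  double zoom_lo = 0.8, zoom_hi = 1.2;
  if (augment) {
    p_fh = as<double>(augspec["flip_h"]);
    p_fv = as<double>(augspec["flip_v"]);
    rot_max = as<double>(augspec["rotation_max"]);
    trans_max = as<double>(augspec["translate_max"]);
    zoom_lo = as<double>(augspec["zoom_min"]);
    zoom_hi = as<double>(augspec["zoom_max"]);
  }

  // Adam state (Keras defaults: beta1 .9, beta2 .999, eps 1e-7, zero decay)
  fvec m(net.nW, arma::fill::zeros), v(net.nW, arma::fill::zeros);
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long tstep = 0;

  std::vector<int> order(nimg);
  for (int i = 0; i < nimg; ++i) order[i] = i;
  int steps = (nimg + batch - 1) / batch;

  NumericVector hloss(epochs), hacc(epochs);
  double best_loss = R_PosInf;
  fvec bestW = Wt, bestS = St;
  int best_epoch = 0;

  std::vector<float> fimg(images.size()), fmsk(masks.size());
  for (R_xlen_t i = 0; i < images.size(); ++i) fimg[i] = (float)images[i];
  for (R_xlen_t i = 0; i < masks.size(); ++i) fmsk[i] = (float)masks[i];

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = nimg - 1; i > 0; --i) {        // Fisher-Yates via R's RNG
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double eloss = 0, eacc = 0;
    for (int st = 0; st < steps; ++st) {
      int b0 = st * batch;
      int bs = std::min(batch, nimg - b0);
      fmat X0(HW * bs, 1), Y0(HW * bs, 1);
      for (int b = 0; b < bs; ++b) {
        const float* is = fimg.data() + (size_t)order[b0 + b] * HW;
        const float* ms = fmsk.data() + (size_t)order[b0 + b] * HW;
        float* id = X0.colptr(0) + (size_t)b * HW;
        float* md = Y0.colptr(0) + (size_t)b * HW;
        if (augment) {
          bool fh = unif_rand() < p_fh, fv = unif_rand() < p_fv;
          double ang = unif_rand() * rot_max;
          double tx = std::floor(unif_rand() * (2 * trans_max + 1)) - trans_max;
          double ty = std::floor(unif_rand() * (2 * trans_max + 1)) - trans_max;
          double zm = zoom_lo + unif_rand() * (zoom_hi - zoom_lo);
          warp_one(is, net.H, net.W, fh, fv, ang, tx, ty, zm, false, id);
          warp_one(ms, net.H, net.W, fh, fv, ang, tx, ty, zm, true, md);
        } else {
          memcpy(id, is, HW * sizeof(float));
          memcpy(md, ms, HW * sizeof(float));
        }
      }
      FwdCache C(net.convs.size(), net.depth - 1);
      fmat z = unet_forward(net, Wt, St, X0, bs, true, &C);
      fmat dz;
      double acc;
      double loss = bce_from_logits(z, Y0, dz, &acc);
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
      fvec G(net.nW, arma::fill::zeros);
      unet_backward(net, Wt, C, dz, bs, G);
      ++tstep;
      double bc1 = 1.0 - std::pow(b1, (double)tstep);
      double bc2 = 1.0 - std::pow(b2, (double)tstep);
      for (int i = 0; i < net.nW; ++i) {
        m[i] = (float)(b1 * m[i] + (1 - b1) * G[i]);
        v[i] = (float)(b2 * v[i] + (1 - b2) * G[i] * G[i]);
        Wt[i] -= (float)(lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps));
      }
      eloss += loss;
      eacc += acc;
    }
    hloss[ep] = eloss / steps;
    hacc[ep] = eacc / steps;
    if (hloss[ep] < best_loss) {
      best_loss = hloss[ep];
      bestW = Wt; bestS = St;
      best_epoch = ep + 1;
    }
    if (verbose)
      Rprintf("epoch %3d/%d  loss %.5f  acc %.5f\n", ep + 1, epochs,
              hloss[ep], hacc[ep]);
    Rcpp::checkUserInterrupt();
  }

  NumericVector outW(net.nW), outS(net.nS);
  for (int i = 0; i < net.nW; ++i) outW[i] = (double)bestW[i];
  for (int i = 0; i < net.nS; ++i) outS[i] = (double)bestS[i];
  return List::create(_["weights"] = outW, _["stats"] = outS,
                      _["loss"] = hloss, _["accuracy"] = hacc,
                      _["best_epoch"] = best_epoch,
                      _["steps_per_epoch"] = steps);
}

// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, bool flip_h, bool flip_v, double angle,
                       double tx, double ty, double zoom, bool nearest) {
  int H = img.nrow(), W = img.ncol();
  std::vector<float> src(H * (size_t)W), dst(H * (size_t)W);
  for (size_t i = 0; i < src.size(); ++i) src[i] = (float)img[i];
  warp_one(src.data(), H, W, flip_h, flip_v, angle, tx, ty, zoom, nearest,
           dst.data());
  NumericMatrix out(H, W);
  for (size_t i = 0; i < dst.size(); ++i) out[i] = (double)dst[i];
  return out;
}
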