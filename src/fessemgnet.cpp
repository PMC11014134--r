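// Dual-task parallel CNN + LSTM network for sEMG time-frequency images:
// four parallel convolutional branches (conv -> batch-norm -> ReLU -> 2x2
// max-pool, four times, dropout after the last pool), a motion head
// (concatenated branch features -> FC -> FC -> softmax over 6 motions) and
// a fatigue head (per-branch two-layer LSTM over feature-map rows, last
// hidden states concatenated -> FC -> FC -> softmax over 3 fatigue states).
// Training minimizes the sum of the two cross-entropies with Adam.
//
// Everything (backprop, Adam, RNG) is self-contained so that runs are
// bit-deterministic given the seed and independent of R's RNG.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct NetConfig {
  int B = 4;          // parallel branches (input images per example)
  int Cin = 3;        // image channels
  int H = 256, W = 256;
  int K = 20;         // conv channels (all four conv layers)
  int motion_fc1 = 2048;
  int n_motion = 6;
  int lstm_hidden = 1024;
  int fatigue_fc1 = 512;
  int n_fatigue = 3;
  double dropout = 0.3;
  int layout = 0;     // 0 = rows_as_steps, 1 = flat_single_step
  int n_conv = 4;
};

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------------------
// small building blocks

static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat cols(9 * C, (size_t)H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int r = c * 9 + ky * 3 + kx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kx - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ky - 1;
            if (si < 0 || si >= H) continue;
            cols(r, (size_t)i + (size_t)j * H) = X(si, sj, c);
          }
        }
      }
  return cols;
}

static void col2im3_accum(const mat& dcols, cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int r = c * 9 + ky * 3 + kx;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kx - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ky - 1;
            if (si < 0 || si >= H) continue;
            dX(si, sj, c) += dcols(r, (size_t)i + (size_t)j * H);
          }
        }
      }
}

// 2x2 max pooling, stride 2; argmax index (within the source slice) kept
// for the backward pass.
static cube maxpool2(const cube& X, ucube& arg) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int h = H / 2, w = W / 2;
  cube Y(h, w, C);
  arg.set_size(h, w, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = X(si, sj, c);
            if (v > best) { best = v; bi = (uword)si + (uword)sj * H; }
          }
        Y(i, j, c) = best;
        arg(i, j, c) = bi;
      }
  return Y;
}

// ---------------------------------------------------------------------------
// parameter store

struct Net {
  NetConfig cfg;
  std::vector<mat> P, G, Ma, Va;     // params, grads, Adam moments
  std::vector<vec> run_mean, run_var; // BN running stats per (branch, layer)
  long adam_t = 0;
  std::mt19937_64 rng;

  // parameter indices
  std::vector<std::vector<int>> conv_w, conv_b, bn_g, bn_b;
  int mot_w1, mot_b1, mot_w2, mot_b2;
  std::vector<std::vector<int>> lstm_wx, lstm_wh, lstm_bi; // [branch][layer]
  int fat_w1, fat_b1, fat_w2, fat_b2;

  int n_lstm_stacks;   // B for rows_as_steps, 1 for flat
  int hF, wF;          // spatial size after 4 pools
  int branch_feat;     // hF * wF * K
  int concat_dim;      // B * branch_feat
  int seq_T, seq_D;    // LSTM sequence layout

  int add_param(int r, int c, double sd, int kind) {
    // kind 0: gaussian sd; 1: zeros; 2: ones; 3: uniform +/- sd
    mat w(r, c);
    if (kind == 1) w.zeros();
    else if (kind == 2) w.ones();
    else {
      std::normal_distribution<double> nd(0.0, sd);
      std::uniform_real_distribution<double> ud(-sd, sd);
      for (uword i = 0; i < w.n_elem; ++i)
        w(i) = (kind == 3) ? ud(rng) : nd(rng);
    }
    P.push_back(w);
    // grad / Adam buffers are sized lazily so that a build-and-predict
    // (e.g. a full-scale shape probe) costs 1x parameter memory, not 4x
    G.push_back(mat());
    Ma.push_back(mat());
    Va.push_back(mat());
    return (int)P.size() - 1;
  }

  void build(const NetConfig& c, unsigned long seed) {
    cfg = c;
    rng.seed(seed);
    if (cfg.H % 16 != 0 || cfg.W % 16 != 0)
      Rcpp::stop("input height/width must be divisible by 16 (four stride-2 poolings)");
    hF = cfg.H / 16; wF = cfg.W / 16;
    branch_feat = hF * wF * cfg.K;
    concat_dim = cfg.B * branch_feat;
    if (cfg.layout == 0) { seq_T = hF; seq_D = wF * cfg.K; n_lstm_stacks = cfg.B; }
    else { seq_T = 1; seq_D = concat_dim; n_lstm_stacks = 1; }

    conv_w.assign(cfg.B, std::vector<int>(cfg.n_conv));
    conv_b = bn_g = bn_b = conv_w;
    run_mean.assign(cfg.B * cfg.n_conv, vec(cfg.K, fill::zeros));
    run_var.assign(cfg.B * cfg.n_conv, vec(cfg.K, fill::ones));
    for (int b = 0; b < cfg.B; ++b)
      for (int l = 0; l < cfg.n_conv; ++l) {
        const int cin = (l == 0) ? cfg.Cin : cfg.K;
        const double sd = std::sqrt(2.0 / (9.0 * cin));
        conv_w[b][l] = add_param(cfg.K, 9 * cin, sd, 0);
        conv_b[b][l] = add_param(cfg.K, 1, 0, 1);
        bn_g[b][l] = add_param(cfg.K, 1, 0, 2);
        bn_b[b][l] = add_param(cfg.K, 1, 0, 1);
      }
    mot_w1 = add_param(cfg.motion_fc1, concat_dim, std::sqrt(2.0 / concat_dim), 0);
    mot_b1 = add_param(cfg.motion_fc1, 1, 0, 1);
    mot_w2 = add_param(cfg.n_motion, cfg.motion_fc1, std::sqrt(2.0 / cfg.motion_fc1), 0);
    mot_b2 = add_param(cfg.n_motion, 1, 0, 1);

    lstm_wx.assign(n_lstm_stacks, std::vector<int>(2));
    lstm_wh = lstm_bi = lstm_wx;
    const int Hd = cfg.lstm_hidden;
    for (int s = 0; s < n_lstm_stacks; ++s)
      for (int l = 0; l < 2; ++l) {
        const int din = (l == 0) ? seq_D : Hd;
        const double sd = 1.0 / std::sqrt((double)Hd);
        lstm_wx[s][l] = add_param(4 * Hd, din, sd, 3);
        lstm_wh[s][l] = add_param(4 * Hd, Hd, sd, 3);
        lstm_bi[s][l] = add_param(4 * Hd, 1, 0, 1);
        P[lstm_bi[s][l]].rows(Hd, 2 * Hd - 1).fill(1.0); // forget-gate bias
      }
    const int fat_in = n_lstm_stacks * Hd;
    fat_w1 = add_param(cfg.fatigue_fc1, fat_in, std::sqrt(2.0 / fat_in), 0);
    fat_b1 = add_param(cfg.fatigue_fc1, 1, 0, 1);
    fat_w2 = add_param(cfg.n_fatigue, cfg.fatigue_fc1, std::sqrt(2.0 / cfg.fatigue_fc1), 0);
    fat_b2 = add_param(cfg.n_fatigue, 1, 0, 1);
  }

  void zero_grads() {
    for (size_t i = 0; i < G.size(); ++i)
      G[i].zeros(P[i].n_rows, P[i].n_cols);
  }
};

// caches for one forward pass
struct BranchCache {
  std::vector<cube> in;       // input of each conv layer
  std::vector<cube> xhat;     // BN normalized
  std::vector<cube> act;      // post-ReLU (pre-pool)
  std::vector<ucube> argm;    // pool argmax
  std::vector<vec> bn_mu, bn_sd;
  cube drop_mask;             // dropout mask on pooled layer-4 output
  vec flat;                   // flattened branch features (after dropout)
};

struct LstmCache {
  // [layer][t]
  mat x;                       // seq_D x T (layer-0 input)
  std::vector<mat> i, f, g, o, c, tc, h; // each: Hd x T per layer
};

struct BatchCache {
  std::vector<std::vector<BranchCache>> br; // [example][branch]
  std::vector<std::vector<LstmCache>> ls;   // [example][stack]
  mat concat;                                // concat_dim x n
  mat mot_a1, mot_r1, mot_p;                 // motion head
  mat fat_in, fat_a1, fat_r1, fat_p;         // fatigue head
};

// ---------------------------------------------------------------------------
// forward

static vec flatten_branch(const cube& Xp) {
  const int h = Xp.n_rows, w = Xp.n_cols, K = Xp.n_slices;
  vec f(h * w * K);
  for (int r = 0; r < h; ++r)
    for (int cc = 0; cc < w; ++cc)
      for (int k = 0; k < K; ++k)
        f((size_t)r * w * K + (size_t)cc * K + k) = Xp(r, cc, k);
  return f;
}

static cube unflatten_branch(const vec& f, int h, int w, int K) {
  cube X(h, w, K);
  for (int r = 0; r < h; ++r)
    for (int cc = 0; cc < w; ++cc)
      for (int k = 0; k < K; ++k)
        X(r, cc, k) = f((size_t)r * w * K + (size_t)cc * K + k);
  return X;
}

// one LSTM layer forward over a sequence; returns h matrix (Hd x T)
static mat lstm_layer_forward(const Net& net, int wx, int wh, int bi,
                              const mat& xseq, mat& gi, mat& gf, mat& gg,
                              mat& go, mat& gc, mat& gtc) {
  const mat& Wx = net.P[wx];
  const mat& Wh = net.P[wh];
  const vec b = net.P[bi].col(0);
  const int Hd = Wh.n_cols, T = xseq.n_cols;
  mat h(Hd, T), dummy;
  gi.set_size(Hd, T); gf.set_size(Hd, T); gg.set_size(Hd, T);
  go.set_size(Hd, T); gc.set_size(Hd, T); gtc.set_size(Hd, T);
  vec hprev(Hd, fill::zeros), cprev(Hd, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = Wx * xseq.col(t) + Wh * hprev + b;
    for (int u = 0; u < Hd; ++u) {
      const double iv = sigm(a(u));
      const double fv = sigm(a(Hd + u));
      const double gv = std::tanh(a(2 * Hd + u));
      const double ov = sigm(a(3 * Hd + u));
      const double cv = fv * cprev(u) + iv * gv;
      const double tcv = std::tanh(cv);
      gi(u, t) = iv; gf(u, t) = fv; gg(u, t) = gv; go(u, t) = ov;
      gc(u, t) = cv; gtc(u, t) = tcv;
      h(u, t) = ov * tcv;
    }
    hprev = h.col(t);
    cprev = gc.col(t);
  }
  return h;
}

// backward through one LSTM layer. dh_ext: Hd x T external gradient on h.
// Returns dx (D x T); accumulates parameter grads.
static mat lstm_layer_backward(Net& net, int wx, int wh, int bi,
                               const mat& xseq, const mat& hseq,
                               const mat& gi, const mat& gf, const mat& gg,
                               const mat& go, const mat& gc, const mat& gtc,
                               const mat& dh_ext) {
  const mat& Wx = net.P[wx];
  const mat& Wh = net.P[wh];
  mat& dWx = net.G[wx];
  mat& dWh = net.G[wh];
  mat& db = net.G[bi];
  const int Hd = Wh.n_cols, T = xseq.n_cols;
  mat dx(xseq.n_rows, T, fill::zeros);
  vec dh_rec(Hd, fill::zeros), dc(Hd, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dh_ext.col(t) + dh_rec;
    vec dov = dh % gtc.col(t);
    dc += dh % go.col(t) % (1.0 - square(gtc.col(t)));
    vec cprev = (t > 0) ? gc.col(t - 1) : vec(Hd, fill::zeros);
    vec div = dc % gg.col(t);
    vec dfv = dc % cprev;
    vec dgv = dc % gi.col(t);
    vec da(4 * Hd);
    da.rows(0, Hd - 1) = div % gi.col(t) % (1.0 - gi.col(t));
    da.rows(Hd, 2 * Hd - 1) = dfv % gf.col(t) % (1.0 - gf.col(t));
    da.rows(2 * Hd, 3 * Hd - 1) = dgv % (1.0 - square(gg.col(t)));
    da.rows(3 * Hd, 4 * Hd - 1) = dov % go.col(t) % (1.0 - go.col(t));
    vec hprev = (t > 0) ? vec(hseq.col(t - 1)) : vec(Hd, fill::zeros);
    dWx += da * xseq.col(t).t();
    dWh += da * hprev.t();
    db.col(0) += da;
    dx.col(t) = Wx.t() * da;
    dh_rec = Wh.t() * da;
    dc = dc % gf.col(t);
  }
  return dx;
}

static mat softmax_cols(const mat& z) {
  mat p = z;
  for (uword j = 0; j < p.n_cols; ++j) {
    const double m = p.col(j).max();
    p.col(j) = exp(p.col(j) - m);
    p.col(j) /= accu(p.col(j));
  }
  return p;
}

// full forward. X: (B*Cin*H*W) x n, column-major per image plane.
static double forward_pass(Net& net, const mat& X,
                           const ivec& ml, const ivec& fl,
                           bool train, bool update_stats, bool use_dropout,
                           BatchCache& bc, double* loss_motion = nullptr,
                           double* loss_fatigue = nullptr) {
  const NetConfig& c = net.cfg;
  const int n = X.n_cols;
  const size_t plane = (size_t)c.H * c.W;
  const size_t img = plane * c.Cin;
  bc.br.assign(n, std::vector<BranchCache>(c.B));

  for (int b = 0; b < c.B; ++b) {
    for (int e = 0; e < n; ++e) {
      BranchCache& bch = bc.br[e][b];
      bch.in.resize(c.n_conv);
      bch.xhat.resize(c.n_conv);
      bch.act.resize(c.n_conv);
      bch.argm.resize(c.n_conv);
      bch.bn_mu.resize(c.n_conv);
      bch.bn_sd.resize(c.n_conv);
      cube X0(c.H, c.W, c.Cin);
      const double* src = X.colptr(e) + (size_t)b * img;
      std::copy(src, src + img, X0.memptr());
      bch.in[0] = std::move(X0);
    }
    // conv stack, whole batch per layer (batch-norm needs batch statistics)
    {
      std::vector<BranchCache*> ptrs(n);
      for (int e = 0; e < n; ++e) ptrs[e] = &bc.br[e][b];
      for (int l = 0; l < c.n_conv; ++l) {
        // --- conv + BN + ReLU + pool over the whole batch ---
        const mat& Wc = net.P[net.conv_w[b][l]];
        const vec bcv = net.P[net.conv_b[b][l]].col(0);
        const vec ga = net.P[net.bn_g[b][l]].col(0);
        const vec be = net.P[net.bn_b[b][l]].col(0);
        const double eps = 1e-5, mom = 0.1;
        std::vector<cube> Y(n);
        for (int e = 0; e < n; ++e) {
          const cube& Xi = ptrs[e]->in[l];
          mat cols = im2col3(Xi);
          mat Ym = Wc * cols;
          Ym.each_col() += bcv;
          Y[e] = cube(Xi.n_rows, Xi.n_cols, c.K);
          for (int k = 0; k < c.K; ++k)
            Y[e].slice(k) = reshape(Ym.row(k), Xi.n_rows, Xi.n_cols);
        }
        vec mu(c.K), var(c.K);
        if (train) {
          const double cnt = (double)n * Y[0].n_rows * Y[0].n_cols;
          for (int k = 0; k < c.K; ++k) {
            double s = 0, s2 = 0;
            for (int e = 0; e < n; ++e) {
              s += accu(Y[e].slice(k));
              s2 += accu(square(Y[e].slice(k)));
            }
            mu(k) = s / cnt;
            var(k) = std::max(0.0, s2 / cnt - mu(k) * mu(k));
          }
          if (update_stats) {
            vec& rm = net.run_mean[b * c.n_conv + l];
            vec& rv = net.run_var[b * c.n_conv + l];
            rm = (1 - mom) * rm + mom * mu;
            rv = (1 - mom) * rv + mom * var;
          }
        } else {
          mu = net.run_mean[b * c.n_conv + l];
          var = net.run_var[b * c.n_conv + l];
        }
        const vec sd = sqrt(var + eps);
        for (int e = 0; e < n; ++e) {
          BranchCache& bch = *ptrs[e];
          cube xh(Y[e].n_rows, Y[e].n_cols, c.K);
          cube a(Y[e].n_rows, Y[e].n_cols, c.K);
          for (int k = 0; k < c.K; ++k) {
            xh.slice(k) = (Y[e].slice(k) - mu(k)) / sd(k);
            a.slice(k) = clamp(ga(k) * xh.slice(k) + be(k), 0.0, datum::inf);
          }
          bch.xhat[l] = std::move(xh);
          bch.act[l] = std::move(a);
          ucube arg;
          cube pooled = maxpool2(bch.act[l], arg);
          bch.argm[l] = std::move(arg);
          if (l + 1 < c.n_conv) bch.in[l + 1] = std::move(pooled);
          else {
            // dropout after the last pooling layer
            if (use_dropout && c.dropout > 0) {
              std::uniform_real_distribution<double> ud(0.0, 1.0);
              cube mask(pooled.n_rows, pooled.n_cols, pooled.n_slices);
              const double keep = 1.0 - c.dropout;
              for (uword q = 0; q < mask.n_elem; ++q)
                mask(q) = (ud(net.rng) < keep) ? 1.0 / keep : 0.0;
              bch.drop_mask = mask;
              pooled %= mask;
            } else {
              bch.drop_mask.set_size(pooled.n_rows, pooled.n_cols, pooled.n_slices);
              bch.drop_mask.ones();
            }
            bch.flat = flatten_branch(pooled);
          }
          bch.bn_mu[l] = mu; bch.bn_sd[l] = sd;
        }
      }
    }
  }

  // motion head
  bc.concat.set_size(net.concat_dim, n);
  for (int e = 0; e < n; ++e)
    for (int b = 0; b < c.B; ++b)
      bc.concat.col(e).rows((size_t)b * net.branch_feat,
                            (size_t)(b + 1) * net.branch_feat - 1) =
        bc.br[e][b].flat;
  bc.mot_a1 = net.P[net.mot_w1] * bc.concat;
  bc.mot_a1.each_col() += net.P[net.mot_b1].col(0);
  bc.mot_r1 = clamp(bc.mot_a1, 0.0, datum::inf);
  mat mz = net.P[net.mot_w2] * bc.mot_r1;
  mz.each_col() += net.P[net.mot_b2].col(0);
  bc.mot_p = softmax_cols(mz);

  // fatigue head
  const int Hd = c.lstm_hidden;
  bc.ls.assign(n, std::vector<LstmCache>(net.n_lstm_stacks * 2));
  bc.fat_in.set_size(net.n_lstm_stacks * Hd, n);
  for (int e = 0; e < n; ++e) {
    for (int s = 0; s < net.n_lstm_stacks; ++s) {
      mat xseq;
      if (c.layout == 0) {
        const vec& f = bc.br[e][s].flat;
        xseq = reshape(f, net.seq_D, net.seq_T); // contiguous wK blocks per row
      } else {
        xseq = bc.concat.col(e);
      }
      LstmCache& L0 = bc.ls[e][2 * s];
      LstmCache& L1 = bc.ls[e][2 * s + 1];
      L0.x = xseq;
      L0.i.resize(1); L0.f.resize(1); L0.g.resize(1); L0.o.resize(1);
      L0.c.resize(1); L0.tc.resize(1); L0.h.resize(1);
      L1.i.resize(1); L1.f.resize(1); L1.g.resize(1); L1.o.resize(1);
      L1.c.resize(1); L1.tc.resize(1); L1.h.resize(1);
      L0.h[0] = lstm_layer_forward(net, net.lstm_wx[s][0], net.lstm_wh[s][0],
                                   net.lstm_bi[s][0], L0.x,
                                   L0.i[0], L0.f[0], L0.g[0], L0.o[0],
                                   L0.c[0], L0.tc[0]);
      L1.x = L0.h[0]; // linear (identity) inter-layer connection
      L1.h[0] = lstm_layer_forward(net, net.lstm_wx[s][1], net.lstm_wh[s][1],
                                   net.lstm_bi[s][1], L1.x,
                                   L1.i[0], L1.f[0], L1.g[0], L1.o[0],
                                   L1.c[0], L1.tc[0]);
      bc.fat_in.col(e).rows((size_t)s * Hd, (size_t)(s + 1) * Hd - 1) =
        L1.h[0].col(net.seq_T - 1);
    }
  }
  bc.fat_a1 = net.P[net.fat_w1] * bc.fat_in;
  bc.fat_a1.each_col() += net.P[net.fat_b1].col(0);
  bc.fat_r1 = clamp(bc.fat_a1, 0.0, datum::inf);
  mat fz = net.P[net.fat_w2] * bc.fat_r1;
  fz.each_col() += net.P[net.fat_b2].col(0);
  bc.fat_p = softmax_cols(fz);

  // loss
  double lm = 0, lf = 0;
  if (ml.n_elem == (uword)n && fl.n_elem == (uword)n) {
    for (int e = 0; e < n; ++e) {
      lm -= std::log(std::max(bc.mot_p(ml(e), e), 1e-12));
      lf -= std::log(std::max(bc.fat_p(fl(e), e), 1e-12));
    }
    lm /= n; lf /= n;
  }
  if (loss_motion) *loss_motion = lm;
  if (loss_fatigue) *loss_fatigue = lf;
  return lm + lf;
}

// ---------------------------------------------------------------------------
// backward

static void backward_pass(Net& net, const mat& X, const ivec& ml,
                          const ivec& fl, BatchCache& bc) {
  const NetConfig& c = net.cfg;
  const int n = X.n_cols;
  const int Hd = c.lstm_hidden;

  // heads
  mat dmz = bc.mot_p;
  mat dfz = bc.fat_p;
  for (int e = 0; e < n; ++e) { dmz(ml(e), e) -= 1.0; dfz(fl(e), e) -= 1.0; }
  dmz /= n; dfz /= n;

  net.G[net.mot_w2] += dmz * bc.mot_r1.t();
  net.G[net.mot_b2].col(0) += sum(dmz, 1);
  mat dr1 = net.P[net.mot_w2].t() * dmz;
  dr1 %= conv_to<mat>::from(bc.mot_a1 > 0);
  net.G[net.mot_w1] += dr1 * bc.concat.t();
  net.G[net.mot_b1].col(0) += sum(dr1, 1);
  mat dconcat = net.P[net.mot_w1].t() * dr1; // concat_dim x n

  net.G[net.fat_w2] += dfz * bc.fat_r1.t();
  net.G[net.fat_b2].col(0) += sum(dfz, 1);
  mat dfr1 = net.P[net.fat_w2].t() * dfz;
  dfr1 %= conv_to<mat>::from(bc.fat_a1 > 0);
  net.G[net.fat_w1] += dfr1 * bc.fat_in.t();
  net.G[net.fat_b1].col(0) += sum(dfr1, 1);
  mat dfat_in = net.P[net.fat_w1].t() * dfr1; // (stacks*Hd) x n

  // LSTM stacks
  for (int e = 0; e < n; ++e) {
    for (int s = 0; s < net.n_lstm_stacks; ++s) {
      LstmCache& L0 = bc.ls[e][2 * s];
      LstmCache& L1 = bc.ls[e][2 * s + 1];
      mat dh1(Hd, net.seq_T, fill::zeros);
      dh1.col(net.seq_T - 1) =
        dfat_in.col(e).rows((size_t)s * Hd, (size_t)(s + 1) * Hd - 1);
      mat dx1 = lstm_layer_backward(net, net.lstm_wx[s][1], net.lstm_wh[s][1],
                                    net.lstm_bi[s][1], L1.x, L1.h[0],
                                    L1.i[0], L1.f[0], L1.g[0], L1.o[0],
                                    L1.c[0], L1.tc[0], dh1);
      mat dx0 = lstm_layer_backward(net, net.lstm_wx[s][0], net.lstm_wh[s][0],
                                    net.lstm_bi[s][0], L0.x, L0.h[0],
                                    L0.i[0], L0.f[0], L0.g[0], L0.o[0],
                                    L0.c[0], L0.tc[0], dx1);
      // route dx0 back into the flattened branch gradient
      if (c.layout == 0) {
        vec df = vectorise(dx0);
        dconcat.col(e).rows((size_t)s * net.branch_feat,
                            (size_t)(s + 1) * net.branch_feat - 1) += df;
      } else {
        dconcat.col(e) += vectorise(dx0);
      }
    }
  }

  // conv branches (batch at a time per branch/layer, reverse order)
  for (int b = 0; b < c.B; ++b) {
    // dflat per example for this branch
    std::vector<cube> dpooled(n);
    for (int e = 0; e < n; ++e) {
      vec df = dconcat.col(e).rows((size_t)b * net.branch_feat,
                                   (size_t)(b + 1) * net.branch_feat - 1);
      cube dp = unflatten_branch(df, net.hF, net.wF, c.K);
      dp %= bc.br[e][b].drop_mask;
      dpooled[e] = std::move(dp);
    }
    for (int l = c.n_conv - 1; l >= 0; --l) {
      const vec ga = net.P[net.bn_g[b][l]].col(0);
      const int Hl = bc.br[0][b].act[l].n_rows;
      const int Wl = bc.br[0][b].act[l].n_cols;
      const double cnt = (double)n * Hl * Wl;
      // pool backward + ReLU backward -> dAct (pre-pool, post-BN-affine)
      std::vector<cube> dY(n);
      // first accumulate dGamma/dBeta terms and the BN reduction sums
      vec sum_dy(c.K, fill::zeros), sum_dy_xhat(c.K, fill::zeros);
      std::vector<cube> dOut(n); // gradient on BN output (post-affine, pre-ReLU... see below)
      for (int e = 0; e < n; ++e) {
        const BranchCache& bch = bc.br[e][b];
        cube da(Hl, Wl, c.K, fill::zeros);
        const ucube& arg = bch.argm[l];
        const cube& dp = dpooled[e];
        for (int k = 0; k < c.K; ++k)
          for (uword j = 0; j < dp.n_cols; ++j)
            for (uword i = 0; i < dp.n_rows; ++i) {
              const uword lin = arg(i, j, k);
              da(lin % Hl, lin / Hl, k) += dp(i, j, k);
            }
        // ReLU mask (act > 0)
        for (int k = 0; k < c.K; ++k)
          da.slice(k) %= conv_to<mat>::from(bch.act[l].slice(k) > 0);
        for (int k = 0; k < c.K; ++k) {
          sum_dy(k) += accu(da.slice(k));
          sum_dy_xhat(k) += accu(da.slice(k) % bch.xhat[l].slice(k));
        }
        dOut[e] = std::move(da);
      }
      net.G[net.bn_g[b][l]].col(0) += sum_dy_xhat;
      net.G[net.bn_b[b][l]].col(0) += sum_dy;
      const vec& sd = bc.br[0][b].bn_sd[l];
      // BN backward -> gradient on conv pre-activation
      mat& dWc = net.G[net.conv_w[b][l]];
      mat& dbc = net.G[net.conv_b[b][l]];
      const mat& Wc = net.P[net.conv_w[b][l]];
      std::vector<cube> dprev(n);
      for (int e = 0; e < n; ++e) {
        const BranchCache& bch = bc.br[e][b];
        cube dz(Hl, Wl, c.K);
        for (int k = 0; k < c.K; ++k)
          dz.slice(k) = (ga(k) / sd(k)) *
            (dOut[e].slice(k) - sum_dy(k) / cnt -
             bch.xhat[l].slice(k) * (sum_dy_xhat(k) / cnt));
        // conv backward
        mat dYm(c.K, (size_t)Hl * Wl);
        for (int k = 0; k < c.K; ++k)
          dYm.row(k) = reshape(dz.slice(k), 1, (size_t)Hl * Wl);
        mat cols = im2col3(bch.in[l]);
        dWc += dYm * cols.t();
        dbc.col(0) += sum(dYm, 1);
        if (l > 0) {
          mat dcols = Wc.t() * dYm;
          cube dX(Hl, Wl, bch.in[l].n_slices, fill::zeros);
          col2im3_accum(dcols, dX);
          dprev[e] = std::move(dX);
        }
      }
      if (l > 0) dpooled = std::move(dprev);
    }
  }
}

// ---------------------------------------------------------------------------
// Adam

static void adam_step(Net& net, double lr, double b1 = 0.9, double b2 = 0.999,
                      double eps = 1e-8) {
  net.adam_t += 1;
  const double c1 = 1.0 - std::pow(b1, (double)net.adam_t);
  const double c2 = 1.0 - std::pow(b2, (double)net.adam_t);
  for (size_t i = 0; i < net.P.size(); ++i) {
    if (net.Ma[i].n_elem == 0) {
      net.Ma[i].zeros(net.P[i].n_rows, net.P[i].n_cols);
      net.Va[i].zeros(net.P[i].n_rows, net.P[i].n_cols);
    }
    net.Ma[i] = b1 * net.Ma[i] + (1 - b1) * net.G[i];
    net.Va[i] = b2 * net.Va[i] + (1 - b2) * square(net.G[i]);
    net.P[i] -= lr * (net.Ma[i] / c1) / (sqrt(net.Va[i] / c2) + eps);
  }
}

// ---------------------------------------------------------------------------
// R interface

static NetConfig config_from_list(Rcpp::List cfg) {
  NetConfig c;
  c.B = Rcpp::as<int>(cfg["n_branches"]);
  c.Cin = Rcpp::as<int>(cfg["in_channels"]);
  c.H = Rcpp::as<int>(cfg["height"]);
  c.W = Rcpp::as<int>(cfg["width"]);
  c.K = Rcpp::as<int>(cfg["conv_channels"]);
  c.motion_fc1 = Rcpp::as<int>(cfg["motion_fc1"]);
  c.n_motion = Rcpp::as<int>(cfg["motion_classes"]);
  c.lstm_hidden = Rcpp::as<int>(cfg["lstm_hidden"]);
  c.fatigue_fc1 = Rcpp::as<int>(cfg["fatigue_fc1"]);
  c.n_fatigue = Rcpp::as<int>(cfg["fatigue_classes"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.layout = Rcpp::as<std::string>(cfg["lstm_sequence_layout"]) ==
             "flat_single_step" ? 1 : 0;
  return c;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(Rcpp::List cfg, int seed) {
  Rcpp::XPtr<Net> p(new Net(), true);
  p->build(config_from_list(cfg), (unsigned long)seed);
  return p;
}

// [[Rcpp::export(name = ".net_n_params")]]
double net_n_params(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  double tot = 0;
  for (auto& w : p->P) tot += (double)w.n_elem;
  return tot;
}

// [[Rcpp::export(name = ".net_predict")]]
Rcpp::List net_predict(SEXP ptr, const arma::mat& X) {
  Rcpp::XPtr<Net> p(ptr);
  BatchCache bc;
  ivec none;
  forward_pass(*p, X, none, none, false, false, false, bc);
  return Rcpp::List::create(
    Rcpp::Named("motion_probs") = bc.mot_p.t(),
    Rcpp::Named("fatigue_probs") = bc.fat_p.t());
}

// [[Rcpp::export(name = ".net_loss")]]
Rcpp::List net_loss(SEXP ptr, const arma::mat& X,
                    const arma::ivec& ml, const arma::ivec& fl,
                    bool train_mode) {
  Rcpp::XPtr<Net> p(ptr);
  BatchCache bc;
  double lm, lf;
  double l = forward_pass(*p, X, ml, fl, train_mode, false, false, bc, &lm, &lf);
  return Rcpp::List::create(Rcpp::Named("loss") = l,
                            Rcpp::Named("loss_motion") = lm,
                            Rcpp::Named("loss_fatigue") = lf);
}

// [[Rcpp::export(name = ".net_backward")]]
double net_backward(SEXP ptr, const arma::mat& X,
                    const arma::ivec& ml, const arma::ivec& fl) {
  Rcpp::XPtr<Net> p(ptr);
  p->zero_grads();
  BatchCache bc;
  double l = forward_pass(*p, X, ml, fl, true, false, false, bc);
  backward_pass(*p, X, ml, fl, bc);
  return l;
}

// [[Rcpp::export(name = ".net_get_params")]]
Rcpp::List net_get_params(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  Rcpp::List out(p->P.size());
  for (size_t i = 0; i < p->P.size(); ++i) out[i] = Rcpp::wrap(p->P[i]);
  return out;
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP ptr, Rcpp::List params) {
  Rcpp::XPtr<Net> p(ptr);
  if ((size_t)params.size() != p->P.size())
    Rcpp::stop("parameter count mismatch");
  for (size_t i = 0; i < p->P.size(); ++i) {
    mat w = Rcpp::as<mat>(params[i]);
    if (w.n_rows != p->P[i].n_rows || w.n_cols != p->P[i].n_cols)
      Rcpp::stop("parameter %d shape mismatch", (int)i);
    p->P[i] = w;
  }
}

// [[Rcpp::export(name = ".net_get_grads")]]
Rcpp::List net_get_grads(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  Rcpp::List out(p->G.size());
  for (size_t i = 0; i < p->G.size(); ++i) out[i] = Rcpp::wrap(p->G[i]);
  return out;
}

// [[Rcpp::export(name = ".net_get_state")]]
Rcpp::List net_get_state(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  Rcpp::List rm(p->run_mean.size()), rv(p->run_var.size());
  for (size_t i = 0; i < p->run_mean.size(); ++i) {
    rm[i] = Rcpp::wrap(p->run_mean[i]);
    rv[i] = Rcpp::wrap(p->run_var[i]);
  }
  return Rcpp::List::create(Rcpp::Named("run_mean") = rm,
                            Rcpp::Named("run_var") = rv);
}

// [[Rcpp::export(name = ".net_set_state")]]
void net_set_state(SEXP ptr, Rcpp::List state) {
  Rcpp::XPtr<Net> p(ptr);
  Rcpp::List rm = state["run_mean"], rv = state["run_var"];
  for (size_t i = 0; i < p->run_mean.size(); ++i) {
    p->run_mean[i] = Rcpp::as<vec>(rm[i]);
    p->run_var[i] = Rcpp::as<vec>(rv[i]);
  }
}

// [[Rcpp::export(name = ".net_train")]]
Rcpp::List net_train(SEXP ptr, const arma::mat& X,
                     const arma::ivec& ml, const arma::ivec& fl,
                     const arma::mat& Xval,
                     const arma::ivec& mlval, const arma::ivec& flval,
                     int epochs, int batch_size, double lr) {
  Rcpp::XPtr<Net> p(ptr);
  Net& net = *p;
  const int n = X.n_cols;
  if (n == 0) Rcpp::stop("empty training set");
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> h_train, h_val, h_macc, h_facc;
  double best_val = datum::inf;
  std::vector<mat> best_P;
  std::vector<vec> best_rm, best_rv;

  for (int ep = 0; ep < epochs; ++ep) {
    // seeded Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> ud(0, i);
      std::swap(order[i], order[ud(net.rng)]);
    }
    double ep_loss = 0; int nb = 0;
    for (int s0 = 0; s0 < n; s0 += batch_size) {
      const int bs = std::min(batch_size, n - s0);
      mat Xb(X.n_rows, bs);
      ivec mb(bs), fb(bs);
      for (int i = 0; i < bs; ++i) {
        Xb.col(i) = X.col(order[s0 + i]);
        mb(i) = ml(order[s0 + i]);
        fb(i) = fl(order[s0 + i]);
      }
      net.zero_grads();
      BatchCache bc;
      double l = forward_pass(net, Xb, mb, fb, true, true, true, bc);
      if (!std::isfinite(l))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      backward_pass(net, Xb, mb, fb, bc);
      adam_step(net, lr);
      ep_loss += l; nb += 1;
      Rcpp::checkUserInterrupt();
    }
    ep_loss /= std::max(nb, 1);

    // validation (eval mode)
    double vl = datum::nan, macc = datum::nan, facc = datum::nan;
    if (Xval.n_cols > 0) {
      BatchCache bc;
      vl = forward_pass(net, Xval, mlval, flval, false, false, false, bc);
      int mok = 0, fok = 0;
      for (uword e = 0; e < Xval.n_cols; ++e) {
        if ((int)bc.mot_p.col(e).index_max() == mlval(e)) mok++;
        if ((int)bc.fat_p.col(e).index_max() == flval(e)) fok++;
      }
      macc = (double)mok / Xval.n_cols;
      facc = (double)fok / Xval.n_cols;
      if (vl < best_val) {
        best_val = vl;
        best_P = net.P;
        best_rm = net.run_mean;
        best_rv = net.run_var;
      }
    }
    h_train.push_back(ep_loss);
    h_val.push_back(vl);
    h_macc.push_back(macc);
    h_facc.push_back(facc);
  }
  if (!best_P.empty()) {
    net.P = best_P;
    net.run_mean = best_rm;
    net.run_var = best_rv;
  }
  return Rcpp::List::create(
    Rcpp::Named("train_loss") = h_train,
    Rcpp::Named("val_loss") = h_val,
    Rcpp::Named("val_motion_acc") = h_macc,
    Rcpp::Named("val_fatigue_acc") = h_facc,
    Rcpp::Named("best_val_loss") = best_val);
}
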