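// Dilated temporal-convolution network for de novo peptide sequencing.
//
// The whole model (forward, backward, RAdam/Adam updates) is implemented
// here by hand on float32 Armadillo matrices. A batch of B spectra of
// padded length L is laid out as a (C x B*L) matrix whose columns are the
// samples' time steps back to back; convolutions are im2col + one GEMM per
// layer, with symmetric zero padding confined to each sample's segment.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fcube;
using arma::frowvec;
using arma::fvec;
using Rcpp::List;
using Rcpp::Named;

// ---------------------------------------------------------------------------
// primitives

// Dilated, symmetrically zero-padded 1-D convolution, computed tap by tap:
// output position t accumulates W_j * x[t + (j - (k-1)/2) * dil] within each
// sample's segment. The weight matrix W is (C_out x C_in*k), tap j being the
// column block j*C_in .. (j+1)*C_in-1.
static fmat conv1d_forward(const fmat& X, const fmat& W, const fvec& b,
                           int k, int dil, int B, int L) {
  const int Cin = X.n_rows;
  const int Cout = W.n_rows;
  fmat Y(Cout, X.n_cols, arma::fill::zeros);
  const int half = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int off = (j - half) * dil;
    const int t0 = std::max(0, -off);
    const int t1 = std::min(L - 1, L - 1 - off);
    if (t0 > t1) continue;
    const fmat Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
    for (int s = 0; s < B; ++s) {
      Y.cols(s * L + t0, s * L + t1) +=
        Wj * X.cols(s * L + t0 + off, s * L + t1 + off);
    }
  }
  Y.each_col() += b;
  return Y;
}

// accumulates dW/db and the input gradient, tap by tap within each
// sample's segment (out-of-segment terms vanish under the zero padding)
static void conv1d_backward(const fmat& dY, const fmat& X, const fmat& W,
                            int k, int dil, int B, int L,
                            fmat& dW, fmat& db, fmat* dX) {
  const int Cin = X.n_rows;
  const int half = (k - 1) / 2;
  db += arma::sum(dY, 1);
  for (int j = 0; j < k; ++j) {
    const int off = (j - half) * dil;
    const int t0 = std::max(0, -off);
    const int t1 = std::min(L - 1, L - 1 - off);
    if (t0 > t1) continue;
    fmat Wj_g(dW.n_rows, Cin, arma::fill::zeros);
    const fmat Wj = W.cols(j * Cin, (j + 1) * Cin - 1);
    for (int s = 0; s < B; ++s) {
      Wj_g += dY.cols(s * L + t0, s * L + t1) *
        X.cols(s * L + t0 + off, s * L + t1 + off).t();
      if (dX) {
        dX->cols(s * L + t0 + off, s * L + t1 + off) +=
          Wj.t() * dY.cols(s * L + t0, s * L + t1);
      }
    }
    dW.cols(j * Cin, (j + 1) * Cin - 1) += Wj_g;
  }
}

struct Param {
  std::string name;
  std::string kind; // weight | bias | ln_gain | ln_bias
  fmat W, g, m, v;
};

struct Config {
  int L = 0, n_blocks = 5, n_layers = 5, kernel = 5;
  std::vector<int> channels;
  int fusion_width = 0, fusion_kernel = 9, fusion_dil2 = 3;
  int meta_in = 10, meta_hidden = 32;
  int out_pos = 32, n_classes = 23;
};

// cache of one conv -> layernorm -> relu unit
struct CLR {
  fmat x_in;     // conv input
  fmat xhat;     // layernorm normalized pre-affine
  frowvec istd;  // per-column inverse std
  fmat out;      // post-relu output
};

struct BlockCache {
  CLR entry;
  std::vector<CLR> clr; // 2 per dilated level
  fmat out;             // block output (pre-pool)
  arma::umat pool_arg;  // argmax offsets of the following max pool
};

struct Cache {
  int B = 0;
  fmat x_in;                       // (4 x B*L)
  std::vector<BlockCache> blocks;
  std::vector<fmat> pooled;        // adaptive-pooled block outputs (C_b x B*32)
  std::vector<arma::umat> pooled_arg;
  fmat fuse_sum;                   // (F x B*32)
  CLR fuse1, fuse2;
  fmat feat;                       // fused feature tensor (F x B*32)
  fmat meta_in;                    // (10 x B)
  fmat meta_act;                   // sigmoid output (M x B)
  fmat dec_in;                     // flattened decoder input (F*32+M x B)
  fmat drop_mask;                  // inverted dropout mask on dec_in
};

struct Model {
  Config cfg;
  std::vector<Param> params;
  std::map<std::string, int> index;
  long step = 0;
  Cache cache;
  bool has_cache = false;

  Param& P(const std::string& n) {
    auto it = index.find(n);
    if (it == index.end()) Rcpp::stop("unknown parameter: " + n);
    return params[it->second];
  }
};

static void add_param(Model& m, const std::string& name, const std::string& kind,
                      int nr, int nc) {
  Param p;
  p.name = name;
  p.kind = kind;
  p.W.zeros(nr, nc);
  p.g.zeros(nr, nc);
  m.index[name] = (int)m.params.size();
  m.params.push_back(std::move(p));
}

static Config parse_config(const List& conf) {
  Config c;
  c.L = Rcpp::as<int>(conf["padded_length"]);
  c.n_blocks = Rcpp::as<int>(conf["n_blocks"]);
  c.n_layers = Rcpp::as<int>(conf["n_layers"]);
  c.kernel = Rcpp::as<int>(conf["kernel"]);
  c.channels = Rcpp::as<std::vector<int> >(conf["channels"]);
  c.fusion_width = Rcpp::as<int>(conf["fusion_width"]);
  c.fusion_kernel = Rcpp::as<int>(conf["fusion_kernel"]);
  c.fusion_dil2 = Rcpp::as<int>(conf["fusion_dilation2"]);
  c.meta_hidden = Rcpp::as<int>(conf["meta_hidden"]);
  c.out_pos = Rcpp::as<int>(conf["output_positions"]);
  c.n_classes = Rcpp::as<int>(conf["output_classes"]);
  if ((int)c.channels.size() != c.n_blocks)
    Rcpp::stop("channels must have one entry per block");
  int down = 1 << (c.n_blocks - 1);
  if (c.L % (down * 2) != 0) Rcpp::stop("padded_length not divisible by 2^n_blocks");
  return c;
}

static void build_params(Model& m) {
  const Config& c = m.cfg;
  int cin = 4;
  for (int b = 0; b < c.n_blocks; ++b) {
    const int C = c.channels[b];
    std::string pre = "block" + std::to_string(b);
    add_param(m, pre + "_entry_W", "weight", C, cin);
    add_param(m, pre + "_entry_b", "bias", C, 1);
    add_param(m, pre + "_entry_ln_g", "ln_gain", C, 1);
    add_param(m, pre + "_entry_ln_b", "ln_bias", C, 1);
    for (int l = 0; l < c.n_layers; ++l) {
      for (int j = 0; j < 2; ++j) {
        std::string q = pre + "_l" + std::to_string(l) + "_c" + std::to_string(j);
        add_param(m, q + "_W", "weight", C, C * c.kernel);
        add_param(m, q + "_b", "bias", C, 1);
        add_param(m, q + "_ln_g", "ln_gain", C, 1);
        add_param(m, q + "_ln_b", "ln_bias", C, 1);
      }
    }
    cin = C;
  }
  const int F = c.fusion_width;
  for (int b = 0; b < c.n_blocks; ++b) {
    std::string pre = "fuse_proj" + std::to_string(b);
    add_param(m, pre + "_W", "weight", F, c.channels[b]);
    add_param(m, pre + "_b", "bias", F, 1);
  }
  for (int j = 0; j < 2; ++j) {
    std::string q = "fuse_conv" + std::to_string(j);
    add_param(m, q + "_W", "weight", F, F * c.fusion_kernel);
    add_param(m, q + "_b", "bias", F, 1);
    add_param(m, q + "_ln_g", "ln_gain", F, 1);
    add_param(m, q + "_ln_b", "ln_bias", F, 1);
  }
  add_param(m, "meta_W", "weight", c.meta_hidden, c.meta_in);
  add_param(m, "meta_b", "bias", c.meta_hidden, 1);
  // per-position linear decoder over the flattened fused tensor + meta
  add_param(m, "dec_W", "weight", c.n_classes * c.out_pos,
            F * c.out_pos + c.meta_hidden);
  add_param(m, "dec_b", "bias", c.n_classes * c.out_pos, 1);
  const int aux_sizes[5] = {1, 30, 20, 20, 400};
  const char* aux_names[5] = {"tryptic", "length", "presence", "comp", "pairs"};
  for (int a = 0; a < 5; ++a) {
    std::string q = std::string("aux_") + aux_names[a];
    add_param(m, q + "_W", "weight", aux_sizes[a], F);
    add_param(m, q + "_b", "bias", aux_sizes[a], 1);
  }
}

// ---------------------------------------------------------------------------
// layer forward/backward

static const float LN_EPS = 1e-5f;

static fmat clr_forward(Model& m, const fmat& x, const std::string& stem,
                        int k, int dil, int B, int L, CLR* cache) {
  const fmat& W = m.P(stem + "_W").W;
  const fvec b = m.P(stem + "_b").W.col(0);
  fmat y;
  if (k == 1) {
    y = W * x;
    y.each_col() += b;
  } else {
    y = conv1d_forward(x, W, b, k, dil, B, L);
  }
  // layer norm over channels at each position
  frowvec mu = arma::mean(y, 0);
  frowvec var = arma::var(y, 1, 0); // population variance
  frowvec istd = 1.0f / arma::sqrt(var + LN_EPS);
  y.each_row() -= mu;
  y.each_row() %= istd;
  if (cache) cache->xhat = y;
  const fvec g = m.P(stem + "_ln_g").W.col(0);
  const fvec lb = m.P(stem + "_ln_b").W.col(0);
  y.each_col() %= g;
  y.each_col() += lb;
  y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (cache) {
    cache->x_in = x;
    cache->istd = istd;
    cache->out = y;
  }
  return y;
}

// returns gradient w.r.t. the unit's input; accumulates parameter grads
static fmat clr_backward(Model& m, const fmat& dout, const std::string& stem,
                         int k, int dil, int B, int L, const CLR& cache) {
  fmat mask = arma::conv_to<fmat>::from(cache.out > 0.0f);
  fmat dy = dout % mask;
  const fvec g = m.P(stem + "_ln_g").W.col(0);
  m.P(stem + "_ln_g").g += arma::sum(dy % cache.xhat, 1);
  m.P(stem + "_ln_b").g += arma::sum(dy, 1);
  fmat dxhat = dy;
  dxhat.each_col() %= g;
  frowvec mean_dxhat = arma::mean(dxhat, 0);
  frowvec mean_dxhat_xhat = arma::mean(dxhat % cache.xhat, 0);
  fmat dpre = dxhat;
  dpre.each_row() -= mean_dxhat;
  fmat centered = cache.xhat;
  centered.each_row() %= mean_dxhat_xhat;
  dpre -= centered;
  dpre.each_row() %= cache.istd;
  const fmat& W = m.P(stem + "_W").W;
  fmat dx(cache.x_in.n_rows, cache.x_in.n_cols, arma::fill::zeros);
  if (k == 1) {
    m.P(stem + "_b").g += arma::sum(dpre, 1);
    m.P(stem + "_W").g += dpre * cache.x_in.t();
    dx = W.t() * dpre;
  } else {
    conv1d_backward(dpre, cache.x_in, W, k, dil, B, L,
                    m.P(stem + "_W").g, m.P(stem + "_b").g, &dx);
  }
  return dx;
}

static fmat maxpool2(const fmat& X, int B, int L, arma::umat* arg) {
  const int C = X.n_rows, Lo = L / 2;
  fmat Y(C, B * Lo);
  if (arg) arg->set_size(C, B * Lo);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < Lo; ++t) {
      const int c0 = s * L + 2 * t;
      for (int ch = 0; ch < C; ++ch) {
        const float a = X(ch, c0), bb = X(ch, c0 + 1);
        const bool right = bb > a;
        Y(ch, s * Lo + t) = right ? bb : a;
        if (arg) (*arg)(ch, s * Lo + t) = right ? 1u : 0u;
      }
    }
  }
  return Y;
}

static fmat maxpool2_backward(const fmat& dY, const arma::umat& arg,
                              int B, int L) {
  const int C = dY.n_rows, Lo = L / 2;
  fmat dX(C, B * L, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < Lo; ++t)
      for (int ch = 0; ch < C; ++ch)
        dX(ch, s * L + 2 * t + arg(ch, s * Lo + t)) += dY(ch, s * Lo + t);
  return dX;
}

// adaptive max pooling from length Lin to length Lout per sample; max (not
// mean) so that sparse peak-driven activations survive the reduction to the
// decoder steps. arg stores the absolute source column per pooled entry.
static fmat adapool(const fmat& X, int B, int Lin, int Lout, arma::umat* arg) {
  const int C = X.n_rows;
  fmat Y(C, B * Lout);
  if (arg) arg->set_size(C, B * Lout);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < Lout; ++t) {
      const int a = (int)std::floor((double)t * Lin / Lout);
      const int e = (int)std::ceil((double)(t + 1) * Lin / Lout);
      for (int ch = 0; ch < C; ++ch) {
        int best = s * Lin + a;
        float v = X(ch, best);
        for (int u = a + 1; u < e; ++u) {
          const float cand = X(ch, s * Lin + u);
          if (cand > v) { v = cand; best = s * Lin + u; }
        }
        Y(ch, s * Lout + t) = v;
        if (arg) (*arg)(ch, s * Lout + t) = (arma::uword)best;
      }
    }
  }
  return Y;
}

static fmat adapool_backward(const fmat& dY, const arma::umat& arg,
                             int B, int Lin) {
  const int C = dY.n_rows;
  fmat dX(C, B * Lin, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int ch = 0; ch < C; ++ch)
      dX(ch, arg(ch, j)) += dY(ch, j);
  return dX;
}

// ---------------------------------------------------------------------------
// model forward / backward

// returns main-head logits (n_classes x out_pos x B) and aux logits
static List model_forward(Model& m, const fmat& X, const fmat& meta,
                          bool training, double dropout) {
  const Config& c = m.cfg;
  const int B = meta.n_cols;
  Cache& K = m.cache;
  K = Cache();
  K.B = B;
  K.x_in = X;
  K.meta_in = meta;
  K.blocks.resize(c.n_blocks);
  K.pooled.resize(c.n_blocks);
  K.pooled_arg.resize(c.n_blocks);

  fmat x = X;
  int L = c.L;
  for (int b = 0; b < c.n_blocks; ++b) {
    BlockCache& bc = K.blocks[b];
    std::string pre = "block" + std::to_string(b);
    x = clr_forward(m, x, pre + "_entry", 1, 1, B, L, training ? &bc.entry : nullptr);
    bc.clr.resize(2 * c.n_layers);
    for (int l = 0; l < c.n_layers; ++l) {
      const int dil = 1 << l;
      std::string q0 = pre + "_l" + std::to_string(l) + "_c0";
      std::string q1 = pre + "_l" + std::to_string(l) + "_c1";
      fmat h = clr_forward(m, x, q0, c.kernel, dil, B, L,
                           training ? &bc.clr[2 * l] : nullptr);
      h = clr_forward(m, h, q1, c.kernel, dil, B, L,
                      training ? &bc.clr[2 * l + 1] : nullptr);
      x += h;
    }
    bc.out = x;
    K.pooled[b] = adapool(x, B, L, c.out_pos,
                          training ? &K.pooled_arg[b] : nullptr);
    if (b + 1 < c.n_blocks) {
      x = maxpool2(x, B, L, training ? &bc.pool_arg : nullptr);
      L /= 2;
    }
  }

  const int F = c.fusion_width;
  fmat S(F, B * c.out_pos, arma::fill::zeros);
  for (int b = 0; b < c.n_blocks; ++b) {
    std::string pre = "fuse_proj" + std::to_string(b);
    fmat t = m.P(pre + "_W").W * K.pooled[b];
    t.each_col() += fvec(m.P(pre + "_b").W.col(0));
    S += t;
  }
  K.fuse_sum = S;
  fmat f = clr_forward(m, S, "fuse_conv0", c.fusion_kernel, 1, B, c.out_pos,
                       training ? &K.fuse1 : nullptr);
  f = clr_forward(m, f, "fuse_conv1", c.fusion_kernel, c.fusion_dil2, B,
                  c.out_pos, training ? &K.fuse2 : nullptr);
  K.feat = f;

  // meta: linear + sigmoid, appended to the flattened fused tensor
  fmat mv = m.P("meta_W").W * meta;
  mv.each_col() += fvec(m.P("meta_b").W.col(0));
  mv = 1.0f / (1.0f + arma::exp(-mv));
  K.meta_act = mv;
  const int M = c.meta_hidden;
  const int D = F * c.out_pos + M;
  fmat Z(D, B);
  for (int s = 0; s < B; ++s) {
    Z.submat(0, s, F * c.out_pos - 1, s) = arma::vectorise(
      f.cols(s * c.out_pos, (s + 1) * c.out_pos - 1));
    Z.submat(F * c.out_pos, s, D - 1, s) = mv.col(s);
  }
  // inverted dropout on the flattened feature part (meta rows kept) --
  // regularizes the wide decoder head against memorization; draws come
  // from R's RNG so runs stay reproducible under set.seed
  if (training && dropout > 0) {
    Rcpp::NumericVector u = Rcpp::runif(F * c.out_pos * B);
    fmat mask(D, B, arma::fill::ones);
    const float keep = 1.0f - (float)dropout;
    int q = 0;
    for (int s = 0; s < B; ++s)
      for (int r = 0; r < F * c.out_pos; ++r, ++q)
        mask(r, s) = (u[q] < keep) ? 1.0f / keep : 0.0f;
    Z %= mask;
    K.drop_mask = mask;
  } else {
    K.drop_mask.reset();
  }
  K.dec_in = Z;

  // per-position linear decoder: rows p*23..p*23+22 of dec_W map the full
  // fused representation to position p's class logits
  fmat logits_mat = m.P("dec_W").W * Z;
  logits_mat.each_col() += fvec(m.P("dec_b").W.col(0));
  fcube logits(c.n_classes, c.out_pos, B);
  for (int s = 0; s < B; ++s)
    logits.slice(s) = arma::reshape(logits_mat.col(s), c.n_classes, c.out_pos);
  Rcpp::NumericVector logits_arr(logits.n_elem);
  logits_arr.attr("dim") =
    Rcpp::IntegerVector::create(logits.n_rows, logits.n_cols, logits.n_slices);
  std::copy(logits.begin(), logits.end(), logits_arr.begin());

  // auxiliary heads from the globally averaged feature tensor
  fmat gfeat(F, B);
  for (int s = 0; s < B; ++s)
    gfeat.col(s) = arma::mean(f.cols(s * c.out_pos, (s + 1) * c.out_pos - 1), 1);
  auto head = [&](const std::string& q) {
    fmat h = m.P(q + "_W").W * gfeat;
    h.each_col() += fvec(m.P(q + "_b").W.col(0));
    return h;
  };
  m.has_cache = training;
  return List::create(
    Named("logits") = logits_arr,
    Named("aux_tryptic") = head("aux_tryptic"),
    Named("aux_length") = head("aux_length"),
    Named("aux_presence") = head("aux_presence"),
    Named("aux_comp") = head("aux_comp"),
    Named("aux_pairs") = head("aux_pairs"));
}

// backward from loss gradients on all head logits; returns gradient w.r.t.
// the input matrix if want_input_grad
static fmat model_backward(Model& m, const fcube& dlogits,
                           const fmat& d_tryptic, const fmat& d_length,
                           const fmat& d_presence, const fmat& d_comp,
                           const fmat& d_pairs, bool want_input_grad) {
  if (!m.has_cache) Rcpp::stop("backward called without a cached forward pass");
  const Config& c = m.cfg;
  Cache& K = m.cache;
  const int B = K.B, F = c.fusion_width, M = c.meta_hidden;

  // decoder head over the flattened fused representation
  fmat dlogits_mat(c.n_classes * c.out_pos, B);
  for (int s = 0; s < B; ++s)
    dlogits_mat.col(s) = arma::vectorise(dlogits.slice(s));
  m.P("dec_W").g += dlogits_mat * K.dec_in.t();
  m.P("dec_b").g += arma::sum(dlogits_mat, 1);
  fmat dZ = m.P("dec_W").W.t() * dlogits_mat;
  if (K.drop_mask.n_elem > 0) dZ %= K.drop_mask;

  // split into the feature-tensor and meta parts
  fmat df(F, B * c.out_pos);
  for (int s = 0; s < B; ++s)
    df.cols(s * c.out_pos, (s + 1) * c.out_pos - 1) = arma::reshape(
      dZ.submat(0, s, F * c.out_pos - 1, s), F, c.out_pos);
  fmat dmv = dZ.rows(F * c.out_pos, F * c.out_pos + M - 1);
  fmat dpre_meta = dmv % K.meta_act % (1.0f - K.meta_act);
  m.P("meta_W").g += dpre_meta * K.meta_in.t();
  m.P("meta_b").g += arma::sum(dpre_meta, 1);

  // aux heads: gradient flows into the global average of the feature tensor
  fmat gfeat(F, B);
  for (int s = 0; s < B; ++s)
    gfeat.col(s) =
      arma::mean(K.feat.cols(s * c.out_pos, (s + 1) * c.out_pos - 1), 1);
  fmat dg(F, B, arma::fill::zeros);
  auto head_bw = [&](const std::string& q, const fmat& dh) {
    if (dh.n_elem == 0) return;
    m.P(q + "_W").g += dh * gfeat.t();
    m.P(q + "_b").g += arma::sum(dh, 1);
    dg += m.P(q + "_W").W.t() * dh;
  };
  head_bw("aux_tryptic", d_tryptic);
  head_bw("aux_length", d_length);
  head_bw("aux_presence", d_presence);
  head_bw("aux_comp", d_comp);
  head_bw("aux_pairs", d_pairs);
  const float inv_pos = 1.0f / c.out_pos;
  for (int s = 0; s < B; ++s)
    df.cols(s * c.out_pos, (s + 1) * c.out_pos - 1).each_col() +=
      fvec(inv_pos * dg.col(s));

  // fusion convs
  fmat dS = clr_backward(m, df, "fuse_conv1", c.fusion_kernel, c.fusion_dil2,
                         B, c.out_pos, K.fuse2);
  dS = clr_backward(m, dS, "fuse_conv0", c.fusion_kernel, 1, B, c.out_pos,
                    K.fuse1);

  // projections and adaptive pools -> per-block output gradients
  std::vector<fmat> dblock_out(c.n_blocks);
  std::vector<int> Ls(c.n_blocks);
  int L = c.L;
  for (int b = 0; b < c.n_blocks; ++b) {
    Ls[b] = L;
    if (b + 1 < c.n_blocks) L /= 2;
  }
  for (int b = 0; b < c.n_blocks; ++b) {
    std::string pre = "fuse_proj" + std::to_string(b);
    m.P(pre + "_W").g += dS * K.pooled[b].t();
    m.P(pre + "_b").g += arma::sum(dS, 1);
    fmat dpool = m.P(pre + "_W").W.t() * dS;
    dblock_out[b] = adapool_backward(dpool, K.pooled_arg[b], B, Ls[b]);
  }

  // blocks in reverse
  fmat dx; // gradient flowing into the current block's output
  for (int b = c.n_blocks - 1; b >= 0; --b) {
    BlockCache& bc = K.blocks[b];
    fmat dout = dblock_out[b];
    if (b + 1 < c.n_blocks) {
      dout += maxpool2_backward(dx, bc.pool_arg, B, Ls[b]);
    }
    std::string pre = "block" + std::to_string(b);
    for (int l = c.n_layers - 1; l >= 0; --l) {
      const int dil = 1 << l;
      std::string q0 = pre + "_l" + std::to_string(l) + "_c0";
      std::string q1 = pre + "_l" + std::to_string(l) + "_c1";
      fmat dh = clr_backward(m, dout, q1, c.kernel, dil, B, Ls[b],
                             bc.clr[2 * l + 1]);
      dh = clr_backward(m, dh, q0, c.kernel, dil, B, Ls[b], bc.clr[2 * l]);
      dout += dh; // residual
    }
    dx = clr_backward(m, dout, pre + "_entry", 1, 1, B, Ls[b], bc.entry);
  }
  if (want_input_grad) return dx;
  return fmat();
}

// ---------------------------------------------------------------------------
// optimizer

static void opt_step(Model& m, double lr, const std::string& optimizer,
                     double weight_decay) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m.step += 1;
  const double t = (double)m.step;
  const double b1t = std::pow(b1, t), b2t = std::pow(b2, t);
  const double rho_inf = 2.0 / (1.0 - b2) - 1.0;
  const double rho_t = rho_inf - 2.0 * t * b2t / (1.0 - b2t);
  double r_t = 0.0;
  bool rectified = false;
  if (optimizer == "radam" && rho_t > 4.0) {
    rectified = true;
    r_t = std::sqrt(((rho_t - 4.0) * (rho_t - 2.0) * rho_inf) /
                    ((rho_inf - 4.0) * (rho_inf - 2.0) * rho_t));
  }
  for (Param& p : m.params) {
    if (p.m.n_elem == 0) {
      p.m.zeros(p.W.n_rows, p.W.n_cols);
      p.v.zeros(p.W.n_rows, p.W.n_cols);
    }
    // decoupled weight decay on weight matrices only
    if (weight_decay > 0 && p.kind == "weight") {
      p.W -= (float)(lr * weight_decay) * p.W;
    }
    p.m = b1 * p.m + (1.0f - b1) * p.g;
    p.v = b2 * p.v + (1.0f - b2) * (p.g % p.g);
    fmat mhat = p.m / (float)(1.0 - b1t);
    if (optimizer == "adam") {
      fmat vhat = p.v / (float)(1.0 - b2t);
      p.W -= (float)lr * (mhat / (arma::sqrt(vhat) + eps));
    } else if (rectified) {
      fmat vhat = arma::sqrt(p.v / (float)(1.0 - b2t)) + eps;
      p.W -= (float)(lr * r_t) * (mhat / vhat);
    } else {
      p.W -= (float)lr * mhat; // un-rectified warmup: SGD with momentum
    }
  }
}

// ---------------------------------------------------------------------------
// R interface

static fmat flatten_input(const Rcpp::NumericVector& x, int L, int* B_out) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != 4 || dim[1] != L)
    Rcpp::stop("input must be an array of dim (4, padded_length, B)");
  const int B = dim[2];
  *B_out = B;
  fmat X(4, B * L);
  const double* ptr = x.begin();
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      for (int ch = 0; ch < 4; ++ch)
        X(ch, s * L + t) = (float)ptr[ch + 4 * t + 4 * L * s];
  return X;
}

// [[Rcpp::export]]
SEXP cn_create(List config) {
  Model* m = new Model();
  m->cfg = parse_config(config);
  build_params(*m);
  Rcpp::XPtr<Model> ptr(m, true);
  return ptr;
}

// [[Rcpp::export]]
List cn_param_manifest(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  const int n = (int)m->params.size();
  Rcpp::CharacterVector name(n), kind(n);
  Rcpp::IntegerVector nr(n), nc(n);
  for (int i = 0; i < n; ++i) {
    name[i] = m->params[i].name;
    kind[i] = m->params[i].kind;
    nr[i] = m->params[i].W.n_rows;
    nc[i] = m->params[i].W.n_cols;
  }
  return List::create(Named("name") = name, Named("kind") = kind,
                      Named("nrow") = nr, Named("ncol") = nc);
}

// [[Rcpp::export]]
void cn_set_weights(SEXP handle, List weights) {
  Rcpp::XPtr<Model> m(handle);
  Rcpp::CharacterVector nm = weights.names();
  for (int i = 0; i < weights.size(); ++i) {
    Param& p = m->P(Rcpp::as<std::string>(nm[i]));
    Rcpp::NumericMatrix w = weights[i];
    if ((int)p.W.n_rows != w.nrow() || (int)p.W.n_cols != w.ncol())
      Rcpp::stop("shape mismatch for parameter " + p.name);
    for (int cidx = 0; cidx < w.ncol(); ++cidx)
      for (int r = 0; r < w.nrow(); ++r)
        p.W(r, cidx) = (float)w(r, cidx);
  }
}

// [[Rcpp::export]]
List cn_get_weights(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  List out(m->params.size());
  Rcpp::CharacterVector nm(m->params.size());
  for (size_t i = 0; i < m->params.size(); ++i) {
    const Param& p = m->params[i];
    Rcpp::NumericMatrix w(p.W.n_rows, p.W.n_cols);
    for (size_t cidx = 0; cidx < p.W.n_cols; ++cidx)
      for (size_t r = 0; r < p.W.n_rows; ++r)
        w(r, cidx) = p.W(r, cidx);
    out[i] = w;
    nm[i] = p.name;
  }
  out.names() = nm;
  return out;
}

// [[Rcpp::export]]
double cn_n_params(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  double n = 0;
  for (const Param& p : m->params) n += p.W.n_elem;
  return n;
}

// [[Rcpp::export]]
List cn_forward(SEXP handle, Rcpp::NumericVector input,
                Rcpp::NumericMatrix meta, bool training,
                double dropout = 0.0) {
  Rcpp::XPtr<Model> m(handle);
  int B = 0;
  fmat X = flatten_input(input, m->cfg.L, &B);
  if (meta.ncol() != B || meta.nrow() != m->cfg.meta_in)
    Rcpp::stop("meta must be (10 x B)");
  fmat Mt(meta.nrow(), meta.ncol());
  for (int c = 0; c < meta.ncol(); ++c)
    for (int r = 0; r < meta.nrow(); ++r) Mt(r, c) = (float)meta(r, c);
  return model_forward(*m, X, Mt, training, dropout);
}

// [[Rcpp::export]]
void cn_zero_grad(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  for (Param& p : m->params) p.g.zeros();
}

static fmat as_fmat(Rcpp::NumericMatrix x) {
  fmat y(x.nrow(), x.ncol());
  for (int c = 0; c < x.ncol(); ++c)
    for (int r = 0; r < x.nrow(); ++r) y(r, c) = (float)x(r, c);
  return y;
}

// [[Rcpp::export]]
Rcpp::NumericVector cn_backward(SEXP handle, Rcpp::NumericVector dlogits,
                                Rcpp::NumericMatrix d_tryptic,
                                Rcpp::NumericMatrix d_length,
                                Rcpp::NumericMatrix d_presence,
                                Rcpp::NumericMatrix d_comp,
                                Rcpp::NumericMatrix d_pairs,
                                bool want_input_grad) {
  Rcpp::XPtr<Model> m(handle);
  Rcpp::IntegerVector dim = dlogits.attr("dim");
  if (dim.size() != 3 || dim[0] != m->cfg.n_classes ||
      dim[1] != m->cfg.out_pos)
    Rcpp::stop("dlogits must be (classes x positions x B)");
  fcube dl(dim[0], dim[1], dim[2]);
  std::copy(dlogits.begin(), dlogits.end(), dl.begin());
  fmat dx = model_backward(*m, dl, as_fmat(d_tryptic), as_fmat(d_length),
                           as_fmat(d_presence), as_fmat(d_comp),
                           as_fmat(d_pairs), want_input_grad);
  if (!want_input_grad) return Rcpp::NumericVector(0);
  const int B = m->cache.B, L = m->cfg.L;
  Rcpp::NumericVector out(4 * L * B);
  out.attr("dim") = Rcpp::IntegerVector::create(4, L, B);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      for (int ch = 0; ch < 4; ++ch)
        out[ch + 4 * t + 4 * L * s] = dx(ch, s * L + t);
  return out;
}

// [[Rcpp::export]]
List cn_get_grads(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  List out(m->params.size());
  Rcpp::CharacterVector nm(m->params.size());
  for (size_t i = 0; i < m->params.size(); ++i) {
    const Param& p = m->params[i];
    Rcpp::NumericMatrix w(p.g.n_rows, p.g.n_cols);
    for (size_t cidx = 0; cidx < p.g.n_cols; ++cidx)
      for (size_t r = 0; r < p.g.n_rows; ++r)
        w(r, cidx) = p.g(r, cidx);
    out[i] = w;
    nm[i] = p.name;
  }
  out.names() = nm;
  return out;
}

// [[Rcpp::export]]
void cn_step(SEXP handle, double lr, std::string optimizer,
             double weight_decay) {
  Rcpp::XPtr<Model> m(handle);
  if (optimizer != "adam" && optimizer != "radam")
    Rcpp::stop("optimizer must be 'adam' or 'radam'");
  opt_step(*m, lr, optimizer, weight_decay);
}

// [[Rcpp::export]]
void cn_free_cache(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  m->cache = Cache();
  m->has_cache = false;
}

// diagnostic access to cached intermediate tensors of the last training
// forward pass (block outputs pooled to the decoder steps, fused tensor)
// [[Rcpp::export]]
List cn_debug_tensors(SEXP handle) {
  Rcpp::XPtr<Model> m(handle);
  if (!m->has_cache) Rcpp::stop("run a training-mode forward first");
  List pooled(m->cfg.n_blocks);
  for (int b = 0; b < m->cfg.n_blocks; ++b)
    pooled[b] = m->cache.pooled[b];
  List blocks(m->cfg.n_blocks);
  for (int b = 0; b < m->cfg.n_blocks; ++b)
    blocks[b] = m->cache.blocks[b].out;
  return List::create(Named("pooled") = pooled,
                      Named("block_out") = blocks,
                      Named("feat") = m->cache.feat,
                      Named("fuse_sum") = m->cache.fuse_sum);
}

// ---------------------------------------------------------------------------
// receptive-field probe: one TCN block topology (two convs per dilated
// level plus residual), single channel, all-ones weights, linear
// activations. Returns the number of input positions with a nonzero
// gradient when a unit gradient is placed at the center output position.

// [[Rcpp::export]]
int cn_rf_probe(int kernel, int n_layers, int L) {
  const int B = 1;
  // the block is linear under unit weights, and the symmetric all-ones
  // kernel is its own transpose, so backpropagating the center delta is a
  // chain of the same convolutions
  const fmat ones_w(1, kernel, arma::fill::ones);
  const fvec zero_b(1, arma::fill::zeros);
  fmat d(1, L, arma::fill::zeros);
  d(0, L / 2) = 1.0f;
  for (int l = n_layers - 1; l >= 0; --l) {
    const int dil = 1 << l;
    // residual level: dx = dout + conv^T(conv^T(dout))
    fmat dh = conv1d_forward(d, ones_w, zero_b, kernel, dil, B, L);
    fmat dh2 = conv1d_forward(dh, ones_w, zero_b, kernel, dil, B, L);
    d += dh2;
  }
  return (int)arma::accu(arma::abs(d) > 0.0f);
}
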