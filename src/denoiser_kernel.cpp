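// Fused forward + backward pass of the denoiser, mirroring the reference
// implementation on the R autodiff tape (R/denoiser.R). The two paths are
// cross-checked in the test suite; this one exists because training runs
// many thousands of small passes and the dense algebra belongs in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// cache: converts each parameter matrix at most once per pass
struct ParamCache {
  const Rcpp::List& P;
  std::map<std::string, mat> cache;
  explicit ParamCache(const Rcpp::List& p) : P(p) {}
  const mat& get(const std::string& name) {
    auto it = cache.find(name);
    if (it != cache.end()) return it->second;
    return cache.emplace(name, Rcpp::as<mat>(P[name])).first->second;
  }
};

// row-wise layer norm; stores normalised rows and the per-row scale
void layernorm_rows(const mat& x, mat& xhat, vec& s, double eps = 1e-5) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  s = sqrt(mean(square(xc), 1) + eps);
  xhat = xc.each_col() / s;
}

// backward of layernorm_rows: g is the gradient wrt xhat
mat layernorm_back(const mat& g, const mat& xhat, const vec& s) {
  vec gm = mean(g, 1);
  vec gx = mean(g % xhat, 1);
  mat out = g.each_col() - gm;
  out -= xhat.each_col() % gx;
  return out.each_col() / s;
}

mat relu_mask(const mat& a) { return conv_to<mat>::from(a > 0.0); }

mat softmax_rows(const mat& x) {
  mat e = exp(x.each_col() - max(x, 1));
  return e.each_col() / sum(e, 1);
}

mat softmax_back(const mat& g, const mat& p) {
  vec dot = sum(g % p, 1);
  return p % (g.each_col() - dot);
}

mat scatter_rows(const mat& m, const uvec& idx, unsigned int n) {
  mat out(n, m.n_cols, fill::zeros);
  for (uword e = 0; e < idx.n_elem; ++e) out.row(idx[e]) += m.row(e);
  return out;
}

struct BranchCache {
  mat msg_in, A1, M, AGG, A2, U;
  bool empty = false;
};

// one message-passing branch (forward); caches every intermediate
void branch_fwd(const mat& H, const uvec& src, const uvec& dst,
                const mat& feat, const mat& W1, const rowvec& b1,
                const mat& W2, const rowvec& b2, BranchCache& C) {
  unsigned int n = H.n_rows;
  if (src.n_elem == 0) {
    C.empty = true;
    C.A2 = repmat(b2, n, 1);
    C.U = clamp(C.A2, 0.0, datum::inf);
    return;
  }
  C.msg_in = join_rows(H.rows(src), feat);
  C.A1 = C.msg_in * W1;
  C.A1.each_row() += b1;
  C.M = clamp(C.A1, 0.0, datum::inf);
  C.AGG = scatter_rows(C.M, dst, n);
  C.A2 = C.AGG * W2;
  C.A2.each_row() += b2;
  C.U = clamp(C.A2, 0.0, datum::inf);
}

struct LayerCache {
  mat Hin, xhat1, Xn, Q, K, V, heads, Hmid, xhat2, Xf, A1, R, FF;
  vec s1, s2;
  std::vector<mat> S;   // per-head attention weights
};

struct BlockCache {
  mat Hin;
  BranchCache L, G;
  mat sl_sg, attn;
};

}  // namespace

// Forward (+ optional backward) of the full denoiser.
// [[Rcpp::export]]
Rcpp::List denoiser_pass_cpp(const Rcpp::List& params_list,
                             int n_blocks, int n_layers, int n_heads,
                             const arma::mat& F, const arma::mat& X,
                             const arma::rowvec& temb, double ab,
                             bool have_ab,
                             const arma::uvec& csrc, const arma::uvec& cdst,
                             const arma::mat& cfeat,
                             const arma::uvec& gsrc, const arma::uvec& gdst,
                             const arma::mat& gfeat,
                             const arma::mat& target, bool with_grad,
                             const std::vector<std::string>& grad_order) {
  const unsigned int n = X.n_rows;
  ParamCache params(params_list);
  const mat& We = params.get("We");
  const rowvec be = params.get("be").row(0);
  const rowvec ge = params.get("ge").row(0);
  const rowvec he = params.get("he").row(0);
  const mat& W_in = params.get("W_in");
  const rowvec b_in = params.get("b_in").row(0);
  const unsigned int h = We.n_cols;
  const unsigned int dk = h / n_heads;

  // ---- encoder ----
  mat enc_lin = X * We;
  enc_lin.each_row() += be;
  mat xhat_e; vec s_e;
  layernorm_rows(enc_lin, xhat_e, s_e);
  mat enc_aff = xhat_e.each_row() % ge;
  enc_aff.each_row() += he;
  mat enc = 1.0 / (1.0 + exp(-enc_aff));
  mat H = F * W_in;
  H.each_row() += b_in;
  H += enc;

  // ---- message-passing blocks ----
  std::vector<BlockCache> blocks(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    BlockCache& BC = blocks[b];
    BC.Hin = H;
    std::string sb = std::to_string(b + 1);
    branch_fwd(H, csrc, cdst, cfeat,
               params.get("Wl1_" + sb), params.get("bl1_" + sb).row(0),
               params.get("Wl2_" + sb), params.get("bl2_" + sb).row(0),
               BC.L);
    branch_fwd(H, gsrc, gdst, gfeat,
               params.get("Wg1_" + sb), params.get("bg1_" + sb).row(0),
               params.get("Wg2_" + sb), params.get("bg2_" + sb).row(0),
               BC.G);
    vec sl = BC.L.U * params.get("wal_" + sb);
    vec sg = BC.G.U * params.get("wag_" + sb);
    BC.sl_sg = join_rows(sl, sg);
    BC.attn = softmax_rows(BC.sl_sg);
    H = BC.Hin + BC.L.U.each_col() % BC.attn.col(0)
               + BC.G.U.each_col() % BC.attn.col(1);
  }

  // ---- transformer refiner ----
  std::vector<LayerCache> layers(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    LayerCache& LC = layers[l];
    std::string sl = std::to_string(l + 1);
    LC.Hin = H;
    layernorm_rows(H, LC.xhat1, LC.s1);
    LC.Xn = LC.xhat1.each_row() % params.get("g1_" + sl).row(0);
    LC.Xn.each_row() += params.get("h1_" + sl).row(0);
    LC.Q = LC.Xn * params.get("Wq_" + sl);
    LC.K = LC.Xn * params.get("Wk_" + sl);
    LC.V = LC.Xn * params.get("Wv_" + sl);
    LC.heads.set_size(n, h);
    LC.S.resize(n_heads);
    for (int hh = 0; hh < n_heads; ++hh) {
      span cols(hh * dk, (hh + 1) * dk - 1);
      mat scores = LC.Q.cols(cols) * LC.K.cols(cols).t() / std::sqrt((double)dk);
      LC.S[hh] = softmax_rows(scores);
      LC.heads.cols(cols) = LC.S[hh] * LC.V.cols(cols);
    }
    H = LC.Hin + LC.heads * params.get("Wo_" + sl);
    LC.Hmid = H;
    layernorm_rows(H, LC.xhat2, LC.s2);
    LC.Xf = LC.xhat2.each_row() % params.get("g2_" + sl).row(0);
    LC.Xf.each_row() += params.get("h2_" + sl).row(0);
    LC.A1 = LC.Xf * params.get("Wf1_" + sl);
    LC.A1.each_row() += params.get("bf1_" + sl).row(0);
    LC.R = clamp(LC.A1, 0.0, datum::inf);
    LC.FF = LC.R * params.get("Wf2_" + sl);
    LC.FF.each_row() += params.get("bf2_" + sl).row(0);
    H += LC.FF;
  }

  // ---- heads ----
  double gain = as_scalar(temb * params.get("w_gain")) +
    params.get("b_gain")(0, 0);
  mat x0hat = H * params.get("W_eps");
  x0hat.each_row() += params.get("b_eps").row(0);
  x0hat += gain * X;
  mat eps;
  if (have_ab) eps = (X - std::sqrt(ab) * x0hat) / std::sqrt(1.0 - ab);
  else eps = x0hat;
  mat atom_logits = H * params.get("W_atom");
  atom_logits.each_row() += params.get("b_atom").row(0);
  mat res_logits = H * params.get("W_res");
  res_logits.each_row() += params.get("b_res").row(0);

  double loss = NA_REAL;
  Rcpp::List grads;
  if (target.n_elem > 0) loss = accu(square(eps - target)) / eps.n_elem;

  if (with_grad) {
    std::map<std::string, mat> G;
    mat d_eps = 2.0 * (eps - target) / (double)eps.n_elem;
    mat d_x0 = have_ab ? mat(-std::sqrt(ab) / std::sqrt(1.0 - ab) * d_eps)
                       : d_eps;
    G["W_eps"] = H.t() * d_x0;
    G["b_eps"] = sum(d_x0, 0);
    double d_gain = accu(d_x0 % X);
    G["w_gain"] = temb.t() * d_gain;
    mat g_gain(1, 1); g_gain(0, 0) = d_gain;
    G["b_gain"] = g_gain;
    G["W_atom"] = mat(size(params.get("W_atom")), fill::zeros);
    G["b_atom"] = mat(1, 3, fill::zeros);
    G["W_res"] = mat(size(params.get("W_res")), fill::zeros);
    G["b_res"] = mat(1, 4, fill::zeros);
    mat dH = d_x0 * params.get("W_eps").t();

    // transformer backward
    for (int l = n_layers - 1; l >= 0; --l) {
      LayerCache& LC = layers[l];
      std::string sl = std::to_string(l + 1);
      // FFN sublayer
      mat dFF = dH;
      G["Wf2_" + sl] = LC.R.t() * dFF;
      G["bf2_" + sl] = sum(dFF, 0);
      mat dR = dFF * params.get("Wf2_" + sl).t();
      mat dA1 = dR % relu_mask(LC.A1);
      G["Wf1_" + sl] = LC.Xf.t() * dA1;
      G["bf1_" + sl] = sum(dA1, 0);
      mat dXf = dA1 * params.get("Wf1_" + sl).t();
      G["g2_" + sl] = sum(dXf % LC.xhat2, 0);
      G["h2_" + sl] = sum(dXf, 0);
      mat dHmid = dH + layernorm_back(dXf.each_row() %
                                      params.get("g2_" + sl).row(0),
                                      LC.xhat2, LC.s2);
      // attention sublayer
      mat dAttnOut = dHmid;
      G["Wo_" + sl] = LC.heads.t() * dAttnOut;
      mat dheads = dAttnOut * params.get("Wo_" + sl).t();
      mat dQ(n, h, fill::zeros), dK(n, h, fill::zeros), dV(n, h, fill::zeros);
      for (int hh = 0; hh < n_heads; ++hh) {
        span cols(hh * dk, (hh + 1) * dk - 1);
        mat dOh = dheads.cols(cols);
        mat dS = dOh * LC.V.cols(cols).t();
        dV.cols(cols) = LC.S[hh].t() * dOh;
        mat dscore = softmax_back(dS, LC.S[hh]) / std::sqrt((double)dk);
        dQ.cols(cols) = dscore * LC.K.cols(cols);
        dK.cols(cols) = dscore.t() * LC.Q.cols(cols);
      }
      G["Wq_" + sl] = LC.Xn.t() * dQ;
      G["Wk_" + sl] = LC.Xn.t() * dK;
      G["Wv_" + sl] = LC.Xn.t() * dV;
      mat dXn = dQ * params.get("Wq_" + sl).t() +
        dK * params.get("Wk_" + sl).t() +
        dV * params.get("Wv_" + sl).t();
      G["g1_" + sl] = sum(dXn % LC.xhat1, 0);
      G["h1_" + sl] = sum(dXn, 0);
      dH = dHmid + layernorm_back(dXn.each_row() %
                                  params.get("g1_" + sl).row(0),
                                  LC.xhat1, LC.s1);
    }

    // message-passing blocks backward
    for (int b = n_blocks - 1; b >= 0; --b) {
      BlockCache& BC = blocks[b];
      std::string sb = std::to_string(b + 1);
      mat dUL = dH.each_col() % BC.attn.col(0);
      mat dUG = dH.each_col() % BC.attn.col(1);
      vec da0 = sum(dH % BC.L.U, 1);
      vec da1 = sum(dH % BC.G.U, 1);
      mat dsc = softmax_back(join_rows(da0, da1), BC.attn);
      dUL += dsc.col(0) * params.get("wal_" + sb).t();
      dUG += dsc.col(1) * params.get("wag_" + sb).t();
      G["wal_" + sb] = BC.L.U.t() * dsc.col(0);
      G["wag_" + sb] = BC.G.U.t() * dsc.col(1);
      mat dHin = dH;   // residual path

      // local branch
      {
        mat dA2 = dUL % relu_mask(BC.L.A2);
        if (BC.L.empty) {
          G["Wl2_" + sb] = mat(size(params.get("Wl2_" + sb)), fill::zeros);
          G["bl2_" + sb] = sum(dA2, 0);
          G["Wl1_" + sb] = mat(size(params.get("Wl1_" + sb)), fill::zeros);
          G["bl1_" + sb] = mat(1, h, fill::zeros);
        } else {
          G["Wl2_" + sb] = BC.L.AGG.t() * dA2;
          G["bl2_" + sb] = sum(dA2, 0);
          mat dAGG = dA2 * params.get("Wl2_" + sb).t();
          mat dM = dAGG.rows(cdst);
          mat dA1 = dM % relu_mask(BC.L.A1);
          G["Wl1_" + sb] = BC.L.msg_in.t() * dA1;
          G["bl1_" + sb] = sum(dA1, 0);
          mat dmsg = dA1 * params.get("Wl1_" + sb).t();
          dHin += scatter_rows(dmsg.cols(0, h - 1), csrc, n);
        }
      }
      // global branch
      {
        mat dA2 = dUG % relu_mask(BC.G.A2);
        if (BC.G.empty) {
          G["Wg2_" + sb] = mat(size(params.get("Wg2_" + sb)), fill::zeros);
          G["bg2_" + sb] = sum(dA2, 0);
          G["Wg1_" + sb] = mat(size(params.get("Wg1_" + sb)), fill::zeros);
          G["bg1_" + sb] = mat(1, h, fill::zeros);
        } else {
          G["Wg2_" + sb] = BC.G.AGG.t() * dA2;
          G["bg2_" + sb] = sum(dA2, 0);
          mat dAGG = dA2 * params.get("Wg2_" + sb).t();
          mat dM = dAGG.rows(gdst);
          mat dA1 = dM % relu_mask(BC.G.A1);
          G["Wg1_" + sb] = BC.G.msg_in.t() * dA1;
          G["bg1_" + sb] = sum(dA1, 0);
          mat dmsg = dA1 * params.get("Wg1_" + sb).t();
          dHin += scatter_rows(dmsg.cols(0, h - 1), gsrc, n);
        }
      }
      dH = dHin;
    }

    // input projection + encoder backward
    G["W_in"] = F.t() * dH;
    G["b_in"] = sum(dH, 0);
    mat denc = dH % enc % (1.0 - enc);
    G["ge"] = sum(denc % xhat_e, 0);
    G["he"] = sum(denc, 0);
    mat dlin = layernorm_back(denc.each_row() % ge, xhat_e, s_e);
    G["We"] = X.t() * dlin;
    G["be"] = sum(dlin, 0);

    if (!grad_order.empty()) {
      // single flat vector in the caller's parameter order
      size_t total = 0;
      for (const auto& nm : grad_order) total += G[nm].n_elem;
      Rcpp::NumericVector flat(total);
      size_t off = 0;
      for (const auto& nm : grad_order) {
        const mat& g = G[nm];
        std::copy(g.memptr(), g.memptr() + g.n_elem, flat.begin() + off);
        off += g.n_elem;
      }
      grads = Rcpp::List::create(Rcpp::Named("flat") = flat);
    } else {
      Rcpp::List out_g;
      for (auto& kv : G) out_g[kv.first] = kv.second;
      grads = out_g;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("eps") = eps,
    Rcpp::Named("x0hat") = x0hat,
    Rcpp::Named("atom_logits") = atom_logits,
    Rcpp::Named("res_logits") = res_logits,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = grads);
}
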