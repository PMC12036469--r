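// Patch-token transformer encoder with multi-task heads.
//
// One 30-s epoch per sample: each channel contributes ten 3-s patches
// (384 samples at 128 Hz) projected by a shared linear layer; per channel the
// ten tokens are followed by a learned SEP token, and a learned CLS token
// closes the sequence (length 11*C + 1). Learned absolute position embeddings
// carry channel identity. Post-layer-norm encoder blocks (attention + GELU
// feed-forward), as in the RoBERTa family. The CLS output feeds three heads:
// 5-class sleep stage (softmax CE), respiratory flag and desaturation flag
// (one logit each, BCE); the training loss is the arithmetic mean of the
// three task losses.
//
// Forward and backward passes are written out explicitly; the analytic
// gradients are checked against finite differences in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

static const double LN_EPS = 1e-5;

struct LnCache { mat xhat; vec istd; };

// Row-wise layer norm. Returns normalized output, fills cache.
static mat layer_norm(const mat &x, const rowvec &g, const rowvec &b, LnCache &c) {
  const uword n = x.n_rows, d = x.n_cols;
  c.xhat.set_size(n, d);
  c.istd.set_size(n);
  mat out(n, d);
  for (uword i = 0; i < n; ++i) {
    const double mu = arma::mean(x.row(i));
    rowvec cen = x.row(i) - mu;
    const double istd = 1.0 / std::sqrt(arma::dot(cen, cen) / d + LN_EPS);
    c.xhat.row(i) = cen * istd;
    c.istd[i] = istd;
    out.row(i) = c.xhat.row(i) % g + b;
  }
  return out;
}

static mat layer_norm_backward(const mat &dy, const rowvec &g, const LnCache &c,
                               rowvec &dg, rowvec &db) {
  const uword n = dy.n_rows, d = dy.n_cols;
  dg += arma::sum(dy % c.xhat, 0);
  db += arma::sum(dy, 0);
  mat dx(n, d);
  for (uword i = 0; i < n; ++i) {
    rowvec dyg = dy.row(i) % g;
    const double m1 = arma::mean(dyg);
    const double m2 = arma::mean(dyg % c.xhat.row(i));
    dx.row(i) = c.istd[i] * (dyg - m1 - c.xhat.row(i) * m2);
  }
  return dx;
}

static mat gelu(const mat &x) {
  mat out(x.n_rows, x.n_cols);
  for (uword i = 0; i < x.n_elem; ++i)
    out[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * M_SQRT1_2));
  return out;
}

static mat gelu_grad(const mat &x) {
  mat out(x.n_rows, x.n_cols);
  const double inv_sqrt_2pi = 0.3989422804014327;
  for (uword i = 0; i < x.n_elem; ++i) {
    const double cdf = 0.5 * (1.0 + std::erf(x[i] * M_SQRT1_2));
    out[i] = cdf + x[i] * inv_sqrt_2pi * std::exp(-0.5 * x[i] * x[i]);
  }
  return out;
}

struct LayerCache {
  mat Xin, Q, K, V, Ctx, Y, F1, G;
  LnCache ln1, ln2;
  arma::cube A;  // (L, L, B*H) attention weights
};

struct Weights {
  mat Wp; rowvec bp, sep, cls, g_emb, b_emb;
  mat pos;
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<rowvec> bq, bk, bv, bo, b1, b2, g1, bln1, g2, bln2;
  mat Ws, Wr, Wd; rowvec bs, br, bd;
  int n_layers, n_heads;
};

static Weights read_weights(const List &w) {
  Weights W;
  W.Wp = as<mat>(w["Wp"]); W.bp = as<rowvec>(w["bp"]);
  W.sep = as<rowvec>(w["sep"]); W.cls = as<rowvec>(w["cls"]);
  W.pos = as<mat>(w["pos"]);
  W.g_emb = as<rowvec>(w["g_emb"]); W.b_emb = as<rowvec>(w["b_emb"]);
  W.n_layers = as<int>(w["n_layers"]);
  W.n_heads = as<int>(w["n_heads"]);
  for (int l = 1; l <= W.n_layers; ++l) {
    const std::string s = std::to_string(l);
    W.Wq.push_back(as<mat>(w["Wq" + s])); W.bq.push_back(as<rowvec>(w["bq" + s]));
    W.Wk.push_back(as<mat>(w["Wk" + s])); W.bk.push_back(as<rowvec>(w["bk" + s]));
    W.Wv.push_back(as<mat>(w["Wv" + s])); W.bv.push_back(as<rowvec>(w["bv" + s]));
    W.Wo.push_back(as<mat>(w["Wo" + s])); W.bo.push_back(as<rowvec>(w["bo" + s]));
    W.W1.push_back(as<mat>(w["W1" + s])); W.b1.push_back(as<rowvec>(w["b1" + s]));
    W.W2.push_back(as<mat>(w["W2" + s])); W.b2.push_back(as<rowvec>(w["b2" + s]));
    W.g1.push_back(as<rowvec>(w["g_ln1" + s])); W.bln1.push_back(as<rowvec>(w["b_ln1" + s]));
    W.g2.push_back(as<rowvec>(w["g_ln2" + s])); W.bln2.push_back(as<rowvec>(w["b_ln2" + s]));
  }
  W.Ws = as<mat>(w["Ws"]); W.bs = as<rowvec>(w["bs"]);
  W.Wr = as<mat>(w["Wr"]); W.br = as<rowvec>(w["br"]);
  W.Wd = as<mat>(w["Wd"]); W.bd = as<rowvec>(w["bd"]);
  return W;
}

// Embed a batch into the stacked token matrix ((B*L) x D).
// X is (patch_len, P, N) as a double array or a float32 buffer;
// idx 0-based sample indices; P = 10*C patches.
static mat embed_tokens(const Weights &W, SEXP X, uword patch_len,
                        uword P, const arma::uvec &idx, uword C,
                        mat &Pmat, LnCache &ln_emb, mat &H0) {
  const uword B = idx.n_elem, D = W.Wp.n_cols;
  const uword L = 11 * C + 1;
  Pmat.set_size(B * P, patch_len);
  if (TYPEOF(X) == REALSXP) {
    const double *xptr = REAL(X);
    for (uword b = 0; b < B; ++b) {
      const double *s = xptr + idx[b] * patch_len * P;
      for (uword p = 0; p < P; ++p)
        Pmat.row(b * P + p) = rowvec(const_cast<double *>(s + p * patch_len),
                                     patch_len, false);
    }
  } else {
    XPtr<std::vector<float>> fp(X);
    const float *xptr = fp->data();
    for (uword b = 0; b < B; ++b) {
      const float *s = xptr + static_cast<size_t>(idx[b]) * patch_len * P;
      for (uword p = 0; p < P; ++p)
        for (uword k = 0; k < patch_len; ++k)
          Pmat(b * P + p, k) = static_cast<double>(s[p * patch_len + k]);
    }
  }
  mat PE = Pmat * W.Wp;
  PE.each_row() += W.bp;
  H0.set_size(B * L, D);
  for (uword b = 0; b < B; ++b) {
    for (uword c = 0; c < C; ++c) {
      for (uword p = 0; p < 10; ++p)
        H0.row(b * L + c * 11 + p) = PE.row(b * P + c * 10 + p);
      H0.row(b * L + c * 11 + 10) = W.sep;
    }
    H0.row(b * L + L - 1) = W.cls;
    H0.rows(b * L, b * L + L - 1) += W.pos;
  }
  return layer_norm(H0, W.g_emb, W.b_emb, ln_emb);
}

static mat encoder_forward(const Weights &W, mat E, uword B, uword L,
                           std::vector<LayerCache> &caches, bool keep_cache) {
  const uword D = E.n_cols;
  const uword H = W.n_heads, dh = D / H;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));
  for (int l = 0; l < W.n_layers; ++l) {
    LayerCache lc;
    lc.Xin = E;
    mat Q = E * W.Wq[l]; Q.each_row() += W.bq[l];
    mat K = E * W.Wk[l]; K.each_row() += W.bk[l];
    mat V = E * W.Wv[l]; V.each_row() += W.bv[l];
    mat Ctx(B * L, D);
    if (keep_cache) lc.A.set_size(L, L, B * H);
    for (uword b = 0; b < B; ++b) {
      for (uword h = 0; h < H; ++h) {
        mat Qb = Q.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat Kb = K.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat Vb = V.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat S = Qb * Kb.t() * scale;
        // row-wise softmax
        for (uword r = 0; r < L; ++r) {
          rowvec sr = S.row(r);
          sr -= sr.max();
          sr = arma::exp(sr);
          S.row(r) = sr / arma::accu(sr);
        }
        Ctx.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1) = S * Vb;
        if (keep_cache) lc.A.slice(b * H + h) = S;
      }
    }
    mat O = Ctx * W.Wo[l];
    O.each_row() += W.bo[l];
    mat R1 = lc.Xin + O;
    mat Y = layer_norm(R1, W.g1[l], W.bln1[l], lc.ln1);
    mat F1 = Y * W.W1[l]; F1.each_row() += W.b1[l];
    mat G = gelu(F1);
    mat F2 = G * W.W2[l]; F2.each_row() += W.b2[l];
    mat R2 = Y + F2;
    E = layer_norm(R2, W.g2[l], W.bln2[l], lc.ln2);
    if (keep_cache) {
      lc.Q = std::move(Q); lc.K = std::move(K); lc.V = std::move(V);
      lc.Ctx = std::move(Ctx); lc.Y = std::move(Y);
      lc.F1 = std::move(F1); lc.G = std::move(G);
      caches.push_back(std::move(lc));
    }
  }
  return E;
}

// Forward pass only: returns CLS embeddings and head logits.
// [[Rcpp::export]]
List cpp_tf_forward(const List &weights, SEXP X,
                    const IntegerVector &dims, const IntegerVector &idx1,
                    int n_channels) {
  Weights W = read_weights(weights);
  const uword patch_len = dims[0], P = dims[1];
  const uword C = n_channels, L = 11 * C + 1, D = W.Wp.n_cols;
  arma::uvec idx(idx1.size());
  for (int i = 0; i < idx1.size(); ++i) idx[i] = idx1[i] - 1;
  const uword B = idx.n_elem;
  mat Pmat, H0;
  LnCache ln_emb;
  std::vector<LayerCache> caches;
  mat E = embed_tokens(W, X, patch_len, P, idx, C, Pmat, ln_emb, H0);
  E = encoder_forward(W, E, B, L, caches, false);
  mat Cls(B, D);
  for (uword b = 0; b < B; ++b) Cls.row(b) = E.row(b * L + L - 1);
  mat ls = Cls * W.Ws; ls.each_row() += W.bs;
  mat lr = Cls * W.Wr; lr.each_row() += W.br;
  mat ld = Cls * W.Wd; ld.each_row() += W.bd;
  return List::create(_["cls"] = Cls, _["stage_logits"] = ls,
                      _["resp_logit"] = lr.col(0), _["desat_logit"] = ld.col(0));
}

// Forward + backward on one batch; returns task losses and gradients.
// stage labels 1..n_stage; resp/desat 0/1.
// [[Rcpp::export]]
List cpp_tf_grad(const List &weights, SEXP X,
                 const IntegerVector &dims, const IntegerVector &idx1,
                 const IntegerVector &stage, const NumericVector &resp,
                 const NumericVector &desat, int n_channels) {
  Weights W = read_weights(weights);
  const uword patch_len = dims[0], P = dims[1];
  const uword C = n_channels, L = 11 * C + 1, D = W.Wp.n_cols;
  const uword H = W.n_heads, dh = D / H;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));
  arma::uvec idx(idx1.size());
  for (int i = 0; i < idx1.size(); ++i) idx[i] = idx1[i] - 1;
  const uword B = idx.n_elem;

  mat Pmat, H0;
  LnCache ln_emb;
  std::vector<LayerCache> caches;
  mat E = embed_tokens(W, X, patch_len, P, idx, C, Pmat, ln_emb, H0);
  E = encoder_forward(W, E, B, L, caches, true);

  mat Cls(B, D);
  for (uword b = 0; b < B; ++b) Cls.row(b) = E.row(b * L + L - 1);
  const uword n_stage = W.Ws.n_cols;
  mat ls = Cls * W.Ws; ls.each_row() += W.bs;
  vec lr = Cls * W.Wr.col(0) + W.br[0];
  vec ld = Cls * W.Wd.col(0) + W.bd[0];

  // losses
  double loss_s = 0.0, loss_r = 0.0, loss_d = 0.0;
  mat Ps(B, n_stage);
  for (uword b = 0; b < B; ++b) {
    rowvec z = ls.row(b);
    z -= z.max();
    rowvec ez = arma::exp(z);
    Ps.row(b) = ez / arma::accu(ez);
    loss_s -= std::log(std::max(Ps(b, stage[b] - 1), 1e-300));
  }
  auto bce = [](double z, double y) {
    // log(1 + exp(z)) - y*z, stable
    return (z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z))) - y * z;
  };
  for (uword b = 0; b < B; ++b) {
    loss_r += bce(lr[b], resp[b]);
    loss_d += bce(ld[b], desat[b]);
  }
  loss_s /= B; loss_r /= B; loss_d /= B;
  const double loss = (loss_s + loss_r + loss_d) / 3.0;

  // head gradients; d(total)/d(logit)
  mat dls = Ps;
  for (uword b = 0; b < B; ++b) dls(b, stage[b] - 1) -= 1.0;
  dls /= (3.0 * B);
  vec dlr(B), dld(B);
  for (uword b = 0; b < B; ++b) {
    dlr[b] = (1.0 / (1.0 + std::exp(-lr[b])) - resp[b]) / (3.0 * B);
    dld[b] = (1.0 / (1.0 + std::exp(-ld[b])) - desat[b]) / (3.0 * B);
  }

  List g = List::create();
  mat gWs = Cls.t() * dls;
  rowvec gbs = arma::sum(dls, 0);
  mat gWr = Cls.t() * dlr;
  mat gWd = Cls.t() * dld;
  mat dCls = dls * W.Ws.t() + dlr * W.Wr.col(0).t() + dld * W.Wd.col(0).t();

  mat dE(B * L, D, arma::fill::zeros);
  for (uword b = 0; b < B; ++b) dE.row(b * L + L - 1) = dCls.row(b);

  // per-layer gradient accumulators
  std::vector<mat> gWq(W.n_layers), gWk(W.n_layers), gWv(W.n_layers),
      gWo(W.n_layers), gW1(W.n_layers), gW2(W.n_layers);
  std::vector<rowvec> gbq(W.n_layers), gbk(W.n_layers), gbv(W.n_layers),
      gbo(W.n_layers), gb1(W.n_layers), gb2(W.n_layers), gg1(W.n_layers),
      gbl1(W.n_layers), gg2(W.n_layers), gbl2(W.n_layers);

  for (int l = W.n_layers - 1; l >= 0; --l) {
    LayerCache &lc = caches[l];
    gg2[l].zeros(D); gbl2[l].zeros(D);
    mat dR2 = layer_norm_backward(dE, W.g2[l], lc.ln2, gg2[l], gbl2[l]);
    mat dY = dR2;                       // residual branch
    mat dF2 = dR2;
    gW2[l] = lc.G.t() * dF2;
    gb2[l] = arma::sum(dF2, 0);
    mat dG = dF2 * W.W2[l].t();
    mat dF1 = dG % gelu_grad(lc.F1);
    gW1[l] = lc.Y.t() * dF1;
    gb1[l] = arma::sum(dF1, 0);
    dY += dF1 * W.W1[l].t();
    gg1[l].zeros(D); gbl1[l].zeros(D);
    mat dR1 = layer_norm_backward(dY, W.g1[l], lc.ln1, gg1[l], gbl1[l]);
    mat dXin = dR1;                     // residual branch
    mat dO = dR1;
    gWo[l] = lc.Ctx.t() * dO;
    gbo[l] = arma::sum(dO, 0);
    mat dCtx = dO * W.Wo[l].t();
    mat dQ(B * L, D, arma::fill::zeros), dK(B * L, D, arma::fill::zeros),
        dV(B * L, D, arma::fill::zeros);
    for (uword b = 0; b < B; ++b) {
      for (uword h = 0; h < H; ++h) {
        mat A = lc.A.slice(b * H + h);
        mat dCtxbh = dCtx.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat Qb = lc.Q.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat Kb = lc.K.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat Vb = lc.V.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1);
        mat dA = dCtxbh * Vb.t();
        dV.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1) = A.t() * dCtxbh;
        vec rs = arma::sum(dA % A, 1);
        mat dS = A % (dA - arma::repmat(rs, 1, L));
        dQ.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1) = dS * Kb * scale;
        dK.submat(b * L, h * dh, b * L + L - 1, h * dh + dh - 1) = dS.t() * Qb * scale;
      }
    }
    gWq[l] = lc.Xin.t() * dQ; gbq[l] = arma::sum(dQ, 0);
    gWk[l] = lc.Xin.t() * dK; gbk[l] = arma::sum(dK, 0);
    gWv[l] = lc.Xin.t() * dV; gbv[l] = arma::sum(dV, 0);
    dXin += dQ * W.Wq[l].t() + dK * W.Wk[l].t() + dV * W.Wv[l].t();
    dE = dXin;
  }

  // embedding backward
  rowvec gg_emb(D, arma::fill::zeros), gb_emb(D, arma::fill::zeros);
  mat dH0 = layer_norm_backward(dE, W.g_emb, ln_emb, gg_emb, gb_emb);
  mat gpos(L, D, arma::fill::zeros);
  rowvec gsep(D, arma::fill::zeros), gcls(D, arma::fill::zeros);
  mat dPE(B * P, D);
  for (uword b = 0; b < B; ++b) {
    gpos += dH0.rows(b * L, b * L + L - 1);
    for (uword c = 0; c < C; ++c) {
      for (uword p = 0; p < 10; ++p)
        dPE.row(b * P + c * 10 + p) = dH0.row(b * L + c * 11 + p);
      gsep += dH0.row(b * L + c * 11 + 10);
    }
    gcls += dH0.row(b * L + L - 1);
  }
  mat gWp = Pmat.t() * dPE;
  rowvec gbp = arma::sum(dPE, 0);

  List grads;
  grads["Wp"] = gWp; grads["bp"] = gbp;
  grads["sep"] = gsep; grads["cls"] = gcls; grads["pos"] = gpos;
  grads["g_emb"] = gg_emb; grads["b_emb"] = gb_emb;
  for (int l = 0; l < W.n_layers; ++l) {
    const std::string s = std::to_string(l + 1);
    grads["Wq" + s] = gWq[l]; grads["bq" + s] = gbq[l];
    grads["Wk" + s] = gWk[l]; grads["bk" + s] = gbk[l];
    grads["Wv" + s] = gWv[l]; grads["bv" + s] = gbv[l];
    grads["Wo" + s] = gWo[l]; grads["bo" + s] = gbo[l];
    grads["W1" + s] = gW1[l]; grads["b1" + s] = gb1[l];
    grads["W2" + s] = gW2[l]; grads["b2" + s] = gb2[l];
    grads["g_ln1" + s] = gg1[l]; grads["b_ln1" + s] = gbl1[l];
    grads["g_ln2" + s] = gg2[l]; grads["b_ln2" + s] = gbl2[l];
  }
  grads["Ws"] = gWs; grads["bs"] = gbs;
  grads["Wr"] = gWr; grads["br"] = rowvec(1, arma::fill::value(arma::accu(dlr)));
  grads["Wd"] = gWd; grads["bd"] = rowvec(1, arma::fill::value(arma::accu(dld)));

  return List::create(_["loss"] = loss, _["loss_stage"] = loss_s,
                      _["loss_resp"] = loss_r, _["loss_desat"] = loss_d,
                      _["grads"] = grads);
}
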