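// Small pre-LayerNorm transformer encoder with a masked-language-model head,
// plus exact reverse-mode gradients. Inputs are cropped to their real length
// before they reach C++, so no padding logic is needed here; attention is
// full (bidirectional) over all supplied tokens.
//
// Parameter list keys (all R matrices; biases are 1 x d):
//   tok_emb (V x H), pos_emb (P x H)
//   per layer i: L<i>_ln1_g, L<i>_ln1_b (1 x H), L<i>_Wq/Wk/Wv/Wo (H x H),
//                L<i>_bq/bk/bv/bo (1 x H), L<i>_ln2_g, L<i>_ln2_b,
//                L<i>_Wf1 (H x I), L<i>_bf1 (1 x I), L<i>_Wf2 (I x H), L<i>_bf2 (1 x H)
//   lnf_g, lnf_b (1 x H), head_W (H x V), head_b (1 x V)
//   classifier (optional): pool_W (H x H), pool_b (1 x H), cls_W (H x C), cls_b (1 x C)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

static arma::mat getp(const List& params, const std::string& key) {
  if (!params.containsElementNamed(key.c_str()))
    stop("missing parameter '%s'", key);
  return as<arma::mat>(params[key]);
}

static std::string lkey(int layer, const char* name) {
  return "L" + std::to_string(layer) + "_" + name;
}

// row-wise layer norm; returns normalized xhat, fills invstd (per row)
static arma::mat layernorm_fwd(const arma::mat& x, arma::vec& invstd) {
  const arma::uword L = x.n_rows;
  arma::mat xhat(L, x.n_cols);
  invstd.set_size(L);
  for (arma::uword i = 0; i < L; ++i) {
    double m = arma::mean(x.row(i));
    arma::rowvec c = x.row(i) - m;
    double v = arma::mean(c % c);
    double is = 1.0 / std::sqrt(v + LN_EPS);
    invstd(i) = is;
    xhat.row(i) = c * is;
  }
  return xhat;
}

// backward through y = xhat % g + b given upstream dy
static arma::mat layernorm_bwd(const arma::mat& dy, const arma::mat& xhat,
                               const arma::vec& invstd, const arma::rowvec& g,
                               arma::rowvec& dg, arma::rowvec& db) {
  dg = arma::sum(dy % xhat, 0);
  db = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= invstd;
  return dx;
}

static arma::mat gelu(const arma::mat& x) {
  arma::mat y = x;
  y.transform([](double v) { return v * 0.5 * (1.0 + std::erf(v * M_SQRT1_2)); });
  return y;
}

static arma::mat gelu_grad(const arma::mat& x) {
  arma::mat y = x;
  y.transform([](double v) {
    double Phi = 0.5 * (1.0 + std::erf(v * M_SQRT1_2));
    double phi = std::exp(-0.5 * v * v) / std::sqrt(2.0 * M_PI);
    return Phi + v * phi;
  });
  return y;
}

static void softmax_rows_inplace(arma::mat& s) {
  for (arma::uword i = 0; i < s.n_rows; ++i) {
    double mx = s.row(i).max();
    arma::rowvec e = arma::exp(s.row(i) - mx);
    s.row(i) = e / arma::accu(e);
  }
}

struct LayerCache {
  arma::mat x_in;           // block input
  arma::mat xhat1; arma::vec invstd1;
  arma::mat x1;             // ln1 output
  arma::mat Q, K, V;        // L x H
  arma::cube A;             // L x L x heads
  arma::mat attn_concat;    // L x H (heads concatenated, pre-Wo)
  arma::mat x_mid;          // after attention residual
  arma::mat xhat2; arma::vec invstd2;
  arma::mat x2;             // ln2 output
  arma::mat ff_pre;         // x2*Wf1 + bf1
  arma::mat ff_act;         // gelu(ff_pre)
};

struct FwdCache {
  arma::mat x0;             // embeddings sum
  std::vector<LayerCache> layers;
  arma::mat xhatf; arma::vec invstdf;
  arma::mat xf;             // final LN output
  arma::uvec ids0;          // 0-based token ids
};

static FwdCache encoder_core(const List& params, const IntegerVector& ids,
                             int n_layers, int n_heads) {
  const arma::uword L = ids.size();
  arma::mat tok = getp(params, "tok_emb");
  arma::mat pos = getp(params, "pos_emb");
  if (L > pos.n_rows) stop("input length %d exceeds max positions %d",
                           (int)L, (int)pos.n_rows);
  const arma::uword H = tok.n_cols;
  if (H % (arma::uword)n_heads != 0) stop("hidden size not divisible by n_heads");
  const arma::uword dh = H / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  FwdCache fc;
  fc.ids0.set_size(L);
  arma::mat x(L, H);
  for (arma::uword i = 0; i < L; ++i) {
    int id = ids[i];
    if (id == NA_INTEGER || id < 1 || (arma::uword)id > tok.n_rows)
      stop("token id out of range at position %d", (int)i + 1);
    fc.ids0(i) = (arma::uword)(id - 1);
    x.row(i) = tok.row(id - 1) + pos.row(i);
  }
  fc.x0 = x;

  fc.layers.resize(n_layers);
  for (int l = 1; l <= n_layers; ++l) {
    LayerCache& c = fc.layers[l - 1];
    c.x_in = x;
    arma::rowvec g1 = getp(params, lkey(l, "ln1_g")).row(0);
    arma::rowvec b1 = getp(params, lkey(l, "ln1_b")).row(0);
    c.xhat1 = layernorm_fwd(x, c.invstd1);
    c.x1 = c.xhat1.each_row() % g1;
    c.x1.each_row() += b1;

    c.Q = c.x1 * getp(params, lkey(l, "Wq"));
    c.Q.each_row() += getp(params, lkey(l, "bq")).row(0);
    c.K = c.x1 * getp(params, lkey(l, "Wk"));
    c.K.each_row() += getp(params, lkey(l, "bk")).row(0);
    c.V = c.x1 * getp(params, lkey(l, "Wv"));
    c.V.each_row() += getp(params, lkey(l, "bv")).row(0);

    c.A.set_size(L, L, n_heads);
    c.attn_concat.set_size(L, H);
    for (int h = 0; h < n_heads; ++h) {
      arma::mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
      arma::mat S = Qh * Kh.t() * scale;
      softmax_rows_inplace(S);
      c.A.slice(h) = S;
      c.attn_concat.cols(h * dh, (h + 1) * dh - 1) = S * Vh;
    }
    arma::mat attn_out = c.attn_concat * getp(params, lkey(l, "Wo"));
    attn_out.each_row() += getp(params, lkey(l, "bo")).row(0);
    c.x_mid = x + attn_out;

    arma::rowvec g2 = getp(params, lkey(l, "ln2_g")).row(0);
    arma::rowvec b2 = getp(params, lkey(l, "ln2_b")).row(0);
    c.xhat2 = layernorm_fwd(c.x_mid, c.invstd2);
    c.x2 = c.xhat2.each_row() % g2;
    c.x2.each_row() += b2;

    c.ff_pre = c.x2 * getp(params, lkey(l, "Wf1"));
    c.ff_pre.each_row() += getp(params, lkey(l, "bf1")).row(0);
    c.ff_act = gelu(c.ff_pre);
    arma::mat ff_out = c.ff_act * getp(params, lkey(l, "Wf2"));
    ff_out.each_row() += getp(params, lkey(l, "bf2")).row(0);
    x = c.x_mid + ff_out;
  }

  arma::rowvec gf = getp(params, "lnf_g").row(0);
  arma::rowvec bf = getp(params, "lnf_b").row(0);
  fc.xhatf = layernorm_fwd(x, fc.invstdf);
  fc.xf = fc.xhatf.each_row() % gf;
  fc.xf.each_row() += bf;
  return fc;
}

// gradient accumulator keyed like params
struct GradStore {
  std::map<std::string, arma::mat> g;
  void add(const std::string& k, const arma::mat& v) {
    auto it = g.find(k);
    if (it == g.end()) g.emplace(k, v); else it->second += v;
  }
  List to_list() const {
    List out;
    for (auto& kv : g) out[kv.first] = wrap(kv.second);
    return out;
  }
};

// backprop from gradient w.r.t. the final-LN output xf down to all encoder
// parameters (embeddings included)
static void encoder_backward(const List& params, const FwdCache& fc,
                             arma::mat dxf, int n_layers, int n_heads,
                             GradStore& gs) {
  const arma::uword L = dxf.n_rows;
  const arma::uword H = dxf.n_cols;
  const arma::uword dh = H / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  arma::rowvec dgf, dbf;
  arma::mat dx = layernorm_bwd(dxf, fc.xhatf, fc.invstdf,
                               getp(params, "lnf_g").row(0), dgf, dbf);
  gs.add("lnf_g", dgf); gs.add("lnf_b", dbf);

  for (int l = n_layers; l >= 1; --l) {
    const LayerCache& c = fc.layers[l - 1];
    // feed-forward sub-block: x = x_mid + gelu(ln2(x_mid) Wf1 + bf1) Wf2 + bf2
    arma::mat Wf2 = getp(params, lkey(l, "Wf2"));
    gs.add(lkey(l, "Wf2"), c.ff_act.t() * dx);
    gs.add(lkey(l, "bf2"), arma::sum(dx, 0));
    arma::mat dact = dx * Wf2.t();
    arma::mat dpre = dact % gelu_grad(c.ff_pre);
    arma::mat Wf1 = getp(params, lkey(l, "Wf1"));
    gs.add(lkey(l, "Wf1"), c.x2.t() * dpre);
    gs.add(lkey(l, "bf1"), arma::sum(dpre, 0));
    arma::mat dx2 = dpre * Wf1.t();
    arma::rowvec dg2, db2;
    arma::mat dx_mid = layernorm_bwd(dx2, c.xhat2, c.invstd2,
                                     getp(params, lkey(l, "ln2_g")).row(0), dg2, db2);
    gs.add(lkey(l, "ln2_g"), dg2); gs.add(lkey(l, "ln2_b"), db2);
    dx_mid += dx;  // residual

    // attention sub-block: x_mid = x_in + (concat_h A_h V_h) Wo + bo
    arma::mat Wo = getp(params, lkey(l, "Wo"));
    gs.add(lkey(l, "Wo"), c.attn_concat.t() * dx_mid);
    gs.add(lkey(l, "bo"), arma::sum(dx_mid, 0));
    arma::mat dconcat = dx_mid * Wo.t();

    arma::mat dQ(L, H, arma::fill::zeros), dK(L, H, arma::fill::zeros),
              dV(L, H, arma::fill::zeros);
    for (int h = 0; h < n_heads; ++h) {
      arma::mat dOh = dconcat.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
      arma::mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
      const arma::mat& A = c.A.slice(h);
      arma::mat dA = dOh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = A.t() * dOh;
      arma::mat dS = A % dA;
      arma::vec rs = arma::sum(dS, 1);
      dS -= A.each_col() % rs;
      dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh * scale;
      dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh * scale;
    }
    arma::mat dx1 = dQ * getp(params, lkey(l, "Wq")).t() +
                    dK * getp(params, lkey(l, "Wk")).t() +
                    dV * getp(params, lkey(l, "Wv")).t();
    gs.add(lkey(l, "Wq"), c.x1.t() * dQ);
    gs.add(lkey(l, "bq"), arma::sum(dQ, 0));
    gs.add(lkey(l, "Wk"), c.x1.t() * dK);
    gs.add(lkey(l, "bk"), arma::sum(dK, 0));
    gs.add(lkey(l, "Wv"), c.x1.t() * dV);
    gs.add(lkey(l, "bv"), arma::sum(dV, 0));

    arma::rowvec dg1, db1;
    arma::mat dx_in = layernorm_bwd(dx1, c.xhat1, c.invstd1,
                                    getp(params, lkey(l, "ln1_g")).row(0), dg1, db1);
    gs.add(lkey(l, "ln1_g"), dg1); gs.add(lkey(l, "ln1_b"), db1);
    dx = dx_in + dx_mid;  // residual
  }

  arma::mat tok = getp(params, "tok_emb");
  arma::mat pos = getp(params, "pos_emb");
  arma::mat dtok(tok.n_rows, tok.n_cols, arma::fill::zeros);
  arma::mat dpos(pos.n_rows, pos.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < L; ++i) {
    dtok.row(fc.ids0(i)) += dx.row(i);
    dpos.row(i) += dx.row(i);
  }
  gs.add("tok_emb", dtok);
  gs.add("pos_emb", dpos);
}

// [[Rcpp::export(name = ".enc_forward")]]
List enc_forward(List params, IntegerVector ids, int n_layers, int n_heads,
                 bool want_hidden, bool want_attention) {
  FwdCache fc = encoder_core(params, ids, n_layers, n_heads);
  arma::mat head_W = getp(params, "head_W");
  arma::mat logits = fc.xf * head_W;
  logits.each_row() += getp(params, "head_b").row(0);

  List out = List::create(_["logits"] = wrap(logits));
  if (want_hidden) {
    // per-layer block outputs; block l's output is block l+1's cached input
    List hs(n_layers + 1);
    for (int l = 0; l < n_layers - 1; ++l) hs[l] = wrap(fc.layers[l + 1].x_in);
    if (n_layers >= 1) {
      // last block output is the input to the final LN: reconstruct
      const LayerCache& c = fc.layers[n_layers - 1];
      arma::mat ff_out = c.ff_act * getp(params, lkey(n_layers, "Wf2"));
      ff_out.each_row() += getp(params, lkey(n_layers, "bf2")).row(0);
      hs[n_layers - 1] = wrap(arma::mat(c.x_mid + ff_out));
    }
    hs[n_layers] = wrap(fc.xf);  // final layer-normed states
    out["hidden"] = hs;
  }
  if (want_attention) {
    List att(n_layers);
    for (int l = 0; l < n_layers; ++l) att[l] = wrap(fc.layers[l].A);
    out["attention"] = att;
  }
  return out;
}

// [[Rcpp::export(name = ".enc_cls_forward")]]
List enc_cls_forward(List params, IntegerVector ids, int n_layers, int n_heads) {
  FwdCache fc = encoder_core(params, ids, n_layers, n_heads);
  arma::rowvec pooled = fc.xf.row(0);
  arma::rowvec t = arma::tanh(pooled * getp(params, "pool_W") +
                              getp(params, "pool_b").row(0));
  arma::rowvec logits = t * getp(params, "cls_W") + getp(params, "cls_b").row(0);
  arma::rowvec e = arma::exp(logits - logits.max());
  arma::rowvec probs = e / arma::accu(e);
  return List::create(_["logits"] = wrap(logits), _["probs"] = wrap(probs));
}

// mean cross-entropy over all labeled tokens of the batch; labels use
// NA_integer_ as the ignore sentinel, otherwise 1-based token ids
// [[Rcpp::export(name = ".enc_mlm_batch_grad")]]
List enc_mlm_batch_grad(List params, List ids_list, List labels_list,
                        int n_layers, int n_heads) {
  int B = ids_list.size();
  if (labels_list.size() != B) stop("ids/labels batch size mismatch");

  // first pass: total labeled count
  int n_lab = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector lab = labels_list[b];
    for (int i = 0; i < lab.size(); ++i) if (lab[i] != NA_INTEGER) ++n_lab;
  }
  if (n_lab == 0) stop("no labeled positions in batch");

  GradStore gs;
  double loss = 0.0;
  arma::mat head_W = getp(params, "head_W");
  arma::rowvec head_b = getp(params, "head_b").row(0);

  for (int b = 0; b < B; ++b) {
    IntegerVector ids = ids_list[b];
    IntegerVector lab = labels_list[b];
    if (lab.size() != ids.size()) stop("labels length mismatch in batch item %d", b + 1);
    FwdCache fc = encoder_core(params, ids, n_layers, n_heads);
    arma::mat logits = fc.xf * head_W;
    logits.each_row() += head_b;
    arma::mat dlogits(logits.n_rows, logits.n_cols, arma::fill::zeros);
    bool any = false;
    for (int i = 0; i < lab.size(); ++i) {
      if (lab[i] == NA_INTEGER) continue;
      int y = lab[i] - 1;
      if (y < 0 || (arma::uword)y >= logits.n_cols) stop("label out of range");
      arma::rowvec row = logits.row(i);
      double mx = row.max();
      arma::rowvec e = arma::exp(row - mx);
      arma::rowvec p = e / arma::accu(e);
      loss += -std::log(std::max(p(y), 1e-300)) / n_lab;
      dlogits.row(i) = p / n_lab;
      dlogits(i, y) -= 1.0 / n_lab;
      any = true;
    }
    if (!any) continue;
    gs.add("head_W", fc.xf.t() * dlogits);
    gs.add("head_b", arma::sum(dlogits, 0));
    arma::mat dxf = dlogits * head_W.t();
    encoder_backward(params, fc, dxf, n_layers, n_heads, gs);
  }
  return List::create(_["loss"] = loss, _["n_labeled"] = n_lab,
                      _["grads"] = gs.to_list());
}

// mean cross-entropy over the batch for first-token-pooled classification
// [[Rcpp::export(name = ".enc_cls_batch_grad")]]
List enc_cls_batch_grad(List params, List ids_list, IntegerVector labels,
                        int n_layers, int n_heads) {
  int B = ids_list.size();
  if (labels.size() != B) stop("ids/labels batch size mismatch");
  GradStore gs;
  double loss = 0.0;
  arma::mat pool_W = getp(params, "pool_W");
  arma::rowvec pool_b = getp(params, "pool_b").row(0);
  arma::mat cls_W = getp(params, "cls_W");
  arma::rowvec cls_b = getp(params, "cls_b").row(0);

  for (int b = 0; b < B; ++b) {
    IntegerVector ids = ids_list[b];
    int y = labels[b] - 1;
    if (y < 0 || (arma::uword)y >= cls_W.n_cols) stop("class label out of range");
    FwdCache fc = encoder_core(params, ids, n_layers, n_heads);
    arma::rowvec pooled = fc.xf.row(0);
    arma::rowvec pre = pooled * pool_W + pool_b;
    arma::rowvec t = arma::tanh(pre);
    arma::rowvec logits = t * cls_W + cls_b;
    double mx = logits.max();
    arma::rowvec e = arma::exp(logits - mx);
    arma::rowvec p = e / arma::accu(e);
    loss += -std::log(std::max(p(y), 1e-300)) / B;

    arma::rowvec dlog = p / B;
    dlog(y) -= 1.0 / B;
    gs.add("cls_W", t.t() * dlog);
    gs.add("cls_b", dlog);
    arma::rowvec dt = dlog * cls_W.t();
    arma::rowvec dpre = dt % (1.0 - t % t);
    gs.add("pool_W", pooled.t() * dpre);
    gs.add("pool_b", dpre);
    arma::mat dxf(fc.xf.n_rows, fc.xf.n_cols, arma::fill::zeros);
    dxf.row(0) = dpre * pool_W.t();
    encoder_backward(params, fc, dxf, n_layers, n_heads, gs);
  }
  return List::create(_["loss"] = loss, _["grads"] = gs.to_list());
}
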