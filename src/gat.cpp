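// Two-layer multi-head graph attention network over a shared topology.
//
// Every patient shares one edge set; only the node-feature matrix differs.
// Layer 1 concatenates K heads, layer 2 averages them; each head applies
// ELU after the attention-weighted aggregation. Graph-level readout is the
// node mean followed by an affine map to class logits.
//
// All node matrices are stored features-by-nodes so the per-edge updates
// touch contiguous columns; work buffers are allocated once and reused
// across patients and epochs. Training is full-batch AdamW (decoupled
// weight decay) on the mean cross-entropy, with optional input-feature
// dropout and early stopping on a held-out validation subset. All
// randomness comes from a private mersenne-twister stream seeded from R.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Topology {
  uvec ei;       // target node of each directed edge (self-loops included)
  uvec ej;       // source node
  uvec rowptr;   // edges with target i are [rowptr[i], rowptr[i+1])
  uword n_nodes() const { return rowptr.n_elem - 1; }
};

Topology make_topology(const Rcpp::IntegerVector& ei, const Rcpp::IntegerVector& ej,
                       const Rcpp::IntegerVector& rowptr) {
  Topology t;
  t.ei = conv_to<uvec>::from(Rcpp::as<std::vector<int>>(ei));
  t.ej = conv_to<uvec>::from(Rcpp::as<std::vector<int>>(ej));
  t.rowptr = conv_to<uvec>::from(Rcpp::as<std::vector<int>>(rowptr));
  return t;
}

// Parameters in one flat list of matrices; attention vectors are column
// matrices. Order: W1[k], a1s[k], a1n[k], W2[k], a2s[k], a2n[k], Wout, bout.
struct ParamSet {
  std::vector<mat> m;
  int K = 0;
  int idx_W1(int k) const { return k; }
  int idx_a1s(int k) const { return K + k; }
  int idx_a1n(int k) const { return 2 * K + k; }
  int idx_W2(int k) const { return 3 * K + k; }
  int idx_a2s(int k) const { return 4 * K + k; }
  int idx_a2n(int k) const { return 5 * K + k; }
  int idx_Wout() const { return 6 * K; }
  int idx_bout() const { return 6 * K + 1; }
  void zeros_like(const ParamSet& o) {
    K = o.K;
    m.resize(o.m.size());
    for (size_t i = 0; i < m.size(); ++i) m[i].zeros(size(o.m[i]));
  }
};

ParamSet params_from_list(const Rcpp::List& L) {
  ParamSet p;
  Rcpp::List W1 = L["W1"], a1s = L["a1s"], a1n = L["a1n"];
  Rcpp::List W2 = L["W2"], a2s = L["a2s"], a2n = L["a2n"];
  p.K = W1.size();
  p.m.resize(6 * p.K + 2);
  for (int k = 0; k < p.K; ++k) {
    p.m[p.idx_W1(k)] = Rcpp::as<mat>(W1[k]);
    p.m[p.idx_a1s(k)] = mat(Rcpp::as<vec>(a1s[k]));
    p.m[p.idx_a1n(k)] = mat(Rcpp::as<vec>(a1n[k]));
    p.m[p.idx_W2(k)] = Rcpp::as<mat>(W2[k]);
    p.m[p.idx_a2s(k)] = mat(Rcpp::as<vec>(a2s[k]));
    p.m[p.idx_a2n(k)] = mat(Rcpp::as<vec>(a2n[k]));
  }
  p.m[p.idx_Wout()] = Rcpp::as<mat>(L["Wout"]);
  p.m[p.idx_bout()] = mat(Rcpp::as<vec>(L["bout"]));
  return p;
}

Rcpp::List params_to_list(const ParamSet& p) {
  int K = p.K;
  Rcpp::List W1(K), a1s(K), a1n(K), W2(K), a2s(K), a2n(K);
  for (int k = 0; k < K; ++k) {
    W1[k] = p.m[p.idx_W1(k)];
    a1s[k] = vec(p.m[p.idx_a1s(k)].col(0));
    a1n[k] = vec(p.m[p.idx_a1n(k)].col(0));
    W2[k] = p.m[p.idx_W2(k)];
    a2s[k] = vec(p.m[p.idx_a2s(k)].col(0));
    a2n[k] = vec(p.m[p.idx_a2n(k)].col(0));
  }
  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("a1s") = a1s, Rcpp::Named("a1n") = a1n,
      Rcpp::Named("W2") = W2, Rcpp::Named("a2s") = a2s, Rcpp::Named("a2n") = a2n,
      Rcpp::Named("Wout") = p.m[p.idx_Wout()],
      Rcpp::Named("bout") = vec(p.m[p.idx_bout()].col(0)));
}

inline double elu(double x) { return x > 0 ? x : std::expm1(x); }

// Per-head work buffers (node matrices are hid x N).
struct HeadState {
  mat Hp, M, dM, dHp;
  vec raw, alpha, dalpha, ss, sn, dss, dsn;
  void resize(uword hid, uword N, uword E) {
    Hp.set_size(hid, N); M.set_size(hid, N);
    dM.set_size(hid, N); dHp.set_size(hid, N);
    raw.set_size(E); alpha.set_size(E); dalpha.set_size(E);
    ss.set_size(N); sn.set_size(N); dss.set_size(N); dsn.set_size(N);
  }
};

struct Workspace {
  mat H0, H1, H1in, H2, dH1in, dH0, dH2;
  vec z, probs, logits, dz;
  std::vector<HeadState> s1, s2;
  void resize(uword Fin, uword hid, uword K, uword C, uword N, uword E) {
    H0.set_size(Fin, N);
    H1.set_size(K * hid, N); H1in.set_size(K * hid, N);
    H2.set_size(hid, N);
    dH1in.set_size(K * hid, N); dH0.set_size(Fin, N); dH2.set_size(hid, N);
    z.set_size(hid); probs.set_size(C); logits.set_size(C); dz.set_size(hid);
    s1.resize(K); s2.resize(K);
    for (uword k = 0; k < K; ++k) { s1[k].resize(hid, N, E); s2[k].resize(hid, N, E); }
  }
};

// One attention head, forward. Ht is layer input (Fin x N); `out` receives
// ELU(M) written into the given row band of the layer output.
void head_forward(const mat& Ht, const mat& W, const mat& as_, const mat& an_,
                  const Topology& top, double slope, HeadState& st,
                  mat& out, uword row0) {
  const uword N = top.n_nodes(), E = top.ei.n_elem, hid = W.n_rows;
  st.Hp = W * Ht;
  st.ss = st.Hp.t() * as_.col(0);
  st.sn = st.Hp.t() * an_.col(0);
  const uword* ei = top.ei.memptr(); const uword* ej = top.ej.memptr();
  for (uword e = 0; e < E; ++e) st.raw(e) = st.ss(ei[e]) + st.sn(ej[e]);
  for (uword i = 0; i < N; ++i) {
    uword b = top.rowptr(i), t = top.rowptr(i + 1);
    if (t == b) continue;
    double mx = -datum::inf;
    for (uword e = b; e < t; ++e) {
      double a = st.raw(e) > 0 ? st.raw(e) : slope * st.raw(e);
      st.alpha(e) = a;
      if (a > mx) mx = a;
    }
    double Z = 0;
    for (uword e = b; e < t; ++e) { st.alpha(e) = std::exp(st.alpha(e) - mx); Z += st.alpha(e); }
    for (uword e = b; e < t; ++e) st.alpha(e) /= Z;
  }
  st.M.zeros();
  for (uword e = 0; e < E; ++e) {
    double* mi = st.M.colptr(ei[e]);
    const double* hj = st.Hp.colptr(ej[e]);
    const double a = st.alpha(e);
    for (uword r = 0; r < hid; ++r) mi[r] += a * hj[r];
  }
  for (uword c = 0; c < N; ++c) {
    const double* mc = st.M.colptr(c);
    double* oc = out.colptr(c) + row0;
    for (uword r = 0; r < hid; ++r) oc[r] = elu(mc[r]);
  }
}

// Backprop one head. dOut is the gradient at the ELU output (band row0 of
// the layer gradient). Accumulates dW/das/dan and adds into dH (Fin x N).
void head_backward(const mat& Ht, const mat& W, const mat& as_, const mat& an_,
                   const Topology& top, double slope, HeadState& st,
                   const mat& dOut, uword row0, mat& dW, mat& das, mat& dan,
                   mat& dH) {
  const uword N = top.n_nodes(), E = top.ei.n_elem, hid = W.n_rows;
  const uword* ei = top.ei.memptr(); const uword* ej = top.ej.memptr();
  for (uword c = 0; c < N; ++c) {
    const double* mc = st.M.colptr(c);
    const double* oc = dOut.colptr(c) + row0;
    double* dc = st.dM.colptr(c);
    for (uword r = 0; r < hid; ++r)
      dc[r] = oc[r] * (mc[r] > 0 ? 1.0 : std::exp(mc[r]));
  }
  st.dHp.zeros();
  for (uword e = 0; e < E; ++e) {
    const double* di = st.dM.colptr(ei[e]);
    const double* hj = st.Hp.colptr(ej[e]);
    double* pj = st.dHp.colptr(ej[e]);
    double acc = 0;
    const double a = st.alpha(e);
    for (uword r = 0; r < hid; ++r) { acc += di[r] * hj[r]; pj[r] += a * di[r]; }
    st.dalpha(e) = acc;
  }
  st.dss.zeros(); st.dsn.zeros();
  for (uword i = 0; i < N; ++i) {
    uword b = top.rowptr(i), t = top.rowptr(i + 1);
    if (t == b) continue;
    double s = 0;
    for (uword e = b; e < t; ++e) s += st.alpha(e) * st.dalpha(e);
    for (uword e = b; e < t; ++e) {
      double de = st.alpha(e) * (st.dalpha(e) - s);
      double draw = de * (st.raw(e) > 0 ? 1.0 : slope);
      st.dss(ei[e]) += draw;
      st.dsn(ej[e]) += draw;
    }
  }
  st.dHp += as_.col(0) * st.dss.t();
  st.dHp += an_.col(0) * st.dsn.t();
  das += st.Hp * st.dss;
  dan += st.Hp * st.dsn;
  dW += st.dHp * Ht.t();
  dH += W.t() * st.dHp;
}

// Forward for one patient. ws.H0 must hold the (possibly dropout-masked)
// input; ws.H1in must hold the (possibly masked) layer-2 input after
// calling the first stage.
void forward_layer1(const ParamSet& p, const Topology& top, double slope,
                    Workspace& ws) {
  const uword hid = p.m[p.idx_W1(0)].n_rows;
  for (int k = 0; k < p.K; ++k)
    head_forward(ws.H0, p.m[p.idx_W1(k)], p.m[p.idx_a1s(k)], p.m[p.idx_a1n(k)],
                 top, slope, ws.s1[k], ws.H1, k * hid);
}

void forward_tail(const ParamSet& p, const Topology& top, double slope,
                  Workspace& ws) {
  const uword hid = p.m[p.idx_W2(0)].n_rows;
  const uword N = top.n_nodes();
  ws.H2.zeros();
  mat tmp(hid, N);
  for (int k = 0; k < p.K; ++k) {
    head_forward(ws.H1in, p.m[p.idx_W2(k)], p.m[p.idx_a2s(k)], p.m[p.idx_a2n(k)],
                 top, slope, ws.s2[k], tmp, 0);
    ws.H2 += tmp;
  }
  ws.H2 /= double(p.K);
  ws.z = mean(ws.H2, 1);
  ws.logits = p.m[p.idx_Wout()] * ws.z + p.m[p.idx_bout()].col(0);
  ws.logits -= ws.logits.max();
  ws.probs = exp(ws.logits);
  ws.probs /= accu(ws.probs);
}

void backward_patient(const ParamSet& p, const Topology& top, double slope,
                      Workspace& ws, const vec& dlogits, ParamSet& g) {
  const uword hid = p.m[p.idx_W1(0)].n_rows;
  const uword N = top.n_nodes();
  g.m[g.idx_Wout()] += dlogits * ws.z.t();
  g.m[g.idx_bout()] += dlogits;
  ws.dz = p.m[p.idx_Wout()].t() * dlogits;
  ws.dH2.each_col() = ws.dz / (double(N) * double(p.K));
  ws.dH1in.zeros();
  for (int k = 0; k < p.K; ++k)
    head_backward(ws.H1in, p.m[p.idx_W2(k)], p.m[p.idx_a2s(k)], p.m[p.idx_a2n(k)],
                  top, slope, ws.s2[k], ws.dH2, 0,
                  g.m[g.idx_W2(k)], g.m[g.idx_a2s(k)], g.m[g.idx_a2n(k)], ws.dH1in);
  ws.dH0.zeros();  // input gradient unused but required by the interface
  for (int k = 0; k < p.K; ++k)
    head_backward(ws.H0, p.m[p.idx_W1(k)], p.m[p.idx_a1s(k)], p.m[p.idx_a1n(k)],
                  top, slope, ws.s1[k], ws.dH1in, k * hid,
                  g.m[g.idx_W1(k)], g.m[g.idx_a1s(k)], g.m[g.idx_a1n(k)], ws.dH0);
}

}  // namespace

// Evaluation-mode forward pass over a batch of patients.
// feats: cube n_nodes x F x n_patients (self-loops included in the edges).
// [[Rcpp::export]]
Rcpp::List gat_forward_cpp(const arma::cube& feats, Rcpp::IntegerVector edge_i,
                           Rcpp::IntegerVector edge_j, Rcpp::IntegerVector rowptr,
                           Rcpp::List params, double leaky_slope,
                           bool return_attention = false) {
  Topology top = make_topology(edge_i, edge_j, rowptr);
  ParamSet p = params_from_list(params);
  const uword P = feats.n_slices, N = top.n_nodes(), E = top.ei.n_elem;
  const uword Fin = feats.n_cols;
  const uword hid = p.m[p.idx_W1(0)].n_rows;
  const uword C = p.m[p.idx_bout()].n_rows;
  Workspace ws;
  ws.resize(Fin, hid, p.K, C, N, E);
  mat probs(P, C);
  mat att1, att2;
  if (return_attention) { att1.zeros(E, p.K); att2.zeros(E, p.K); }
  for (uword s = 0; s < P; ++s) {
    ws.H0 = feats.slice(s).t();
    forward_layer1(p, top, leaky_slope, ws);
    ws.H1in = ws.H1;
    forward_tail(p, top, leaky_slope, ws);
    probs.row(s) = ws.probs.t();
    if (return_attention)
      for (int k = 0; k < p.K; ++k) {
        att1.col(k) += ws.s1[k].alpha;
        att2.col(k) += ws.s2[k].alpha;
      }
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs);
  if (return_attention) {
    att1 /= double(P); att2 /= double(P);
    out["attention1"] = att1;
    out["attention2"] = att2;
  }
  return out;
}

// Full-batch AdamW training with optional input dropout and early stopping.
// y: 0-based class labels; val_idx: 0-based patient indices held out for
// early stopping (may be empty). Returns trained parameters plus loss
// histories.
// [[Rcpp::export]]
Rcpp::List gat_train_cpp(const arma::cube& feats, Rcpp::IntegerVector y,
                         Rcpp::IntegerVector edge_i, Rcpp::IntegerVector edge_j,
                         Rcpp::IntegerVector rowptr, Rcpp::List init_params,
                         double leaky_slope, double dropout, double lr,
                         double weight_decay, int epochs, int patience,
                         Rcpp::IntegerVector val_idx, int seed) {
  Topology top = make_topology(edge_i, edge_j, rowptr);
  ParamSet p = params_from_list(init_params);
  const uword P = feats.n_slices, N = top.n_nodes(), E = top.ei.n_elem;
  const uword Fin = feats.n_cols;
  const uword hid = p.m[p.idx_W1(0)].n_rows;
  const uword C = p.m[p.idx_bout()].n_rows;
  Workspace ws;
  ws.resize(Fin, hid, p.K, C, N, E);

  std::vector<bool> is_val(P, false);
  for (int i = 0; i < val_idx.size(); ++i) is_val[val_idx[i]] = true;
  std::vector<uword> tr, va;
  for (uword s = 0; s < P; ++s) (is_val[s] ? va : tr).push_back(s);
  if (tr.empty()) Rcpp::stop("no training graphs left after the validation split");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;

  ParamSet g, m1, m2;
  g.zeros_like(p); m1.zeros_like(p); m2.zeros_like(p);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<double> tr_hist, va_hist;
  double best_val = datum::inf;
  int since_best = 0, best_epoch = -1;
  ParamSet best = p;
  vec dlogits(C);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t i = 0; i < g.m.size(); ++i) g.m[i].zeros();
    double loss = 0;
    for (uword idx = 0; idx < tr.size(); ++idx) {
      uword s = tr[idx];
      ws.H0 = feats.slice(s).t();
      if (dropout > 0)
        for (uword q = 0; q < ws.H0.n_elem; ++q)
          ws.H0(q) = unif(rng) < dropout ? 0.0 : ws.H0(q) / keep;
      forward_layer1(p, top, leaky_slope, ws);
      ws.H1in = ws.H1;
      if (dropout > 0)
        for (uword q = 0; q < ws.H1in.n_elem; ++q)
          ws.H1in(q) = unif(rng) < dropout ? 0.0 : ws.H1in(q) / keep;
      forward_tail(p, top, leaky_slope, ws);
      int yi = y[s];
      loss += -std::log(std::max(ws.probs(yi), 1e-12));
      dlogits = ws.probs;
      dlogits(yi) -= 1.0;
      dlogits /= double(tr.size());
      backward_patient(p, top, leaky_slope, ws, dlogits, g);
    }
    loss /= double(tr.size());
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    tr_hist.push_back(loss);

    const double bc1 = 1.0 - std::pow(b1, ep + 1);
    const double bc2 = 1.0 - std::pow(b2, ep + 1);
    for (size_t i = 0; i < p.m.size(); ++i) {
      const double wd = (int(i) == p.idx_bout()) ? 0.0 : weight_decay;
      m1.m[i] = b1 * m1.m[i] + (1 - b1) * g.m[i];
      m2.m[i] = b2 * m2.m[i] + (1 - b2) * square(g.m[i]);
      p.m[i] -= lr * ((m1.m[i] / bc1) / (sqrt(m2.m[i] / bc2) + eps) + wd * p.m[i]);
    }

    if (!va.empty() && patience > 0) {
      double vl = 0;
      for (uword idx = 0; idx < va.size(); ++idx) {
        uword s = va[idx];
        ws.H0 = feats.slice(s).t();
        forward_layer1(p, top, leaky_slope, ws);
        ws.H1in = ws.H1;
        forward_tail(p, top, leaky_slope, ws);
        vl += -std::log(std::max(ws.probs(y[s]), 1e-12));
      }
      vl /= double(va.size());
      va_hist.push_back(vl);
      if (vl < best_val - 1e-9) {
        best_val = vl; best = p; since_best = 0; best_epoch = ep;
      } else if (++since_best >= patience) {
        p = best;
        break;
      }
    }
  }
  if (!va.empty() && patience > 0 && best_epoch >= 0 && since_best < patience)
    p = best;  // epoch limit reached: restore the best checkpoint
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(p),
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = va_hist,
      Rcpp::Named("best_epoch") = best_epoch + 1);
}
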