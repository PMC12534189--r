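// Set-transformer core for formulation scoring: batched forward pass,
// exact reverse-mode gradients for the ranking / regression objectives,
// and embedding-level gradients for integrated-gradients attribution.
//
// Parameters live in one flat numeric vector; the R side owns the layout
// (comet_param_layout()) and passes 0-based offsets. Weight tensors are
// accessed through non-owning Armadillo views constructed in place at the
// use site (storing such views in structs would copy the memory and, for
// gradients, silently detach the writes).
//
// Token sequence per formulation i (rows of X, contiguous):
//   [ component tokens (n_i) | N/P token | phase token | CLS_1..CLS_T ]
// Pre-LayerNorm blocks: x + Attn(LN(x)); x + MLP(LN(x)); final LN before
// the per-task prediction heads. No positional encoding: tokens are a set.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

struct Dims {
  int d_mol, d_comp, d_type, d_in, d_token, n_types, n_phases, n_tasks;
  int n_blocks, n_heads, dk, mlp, hh;
};

static Dims read_dims(const List& cfg) {
  Dims d;
  d.d_mol = cfg["d_mol"]; d.d_comp = cfg["d_comp"]; d.d_type = cfg["d_type"];
  d.d_token = cfg["d_token"]; d.n_types = cfg["n_types"];
  d.n_phases = cfg["n_phases"]; d.n_tasks = cfg["n_tasks"];
  d.n_blocks = cfg["n_blocks"]; d.n_heads = cfg["n_heads"];
  d.mlp = cfg["mlp_hidden"]; d.hh = cfg["head_hidden"];
  d.d_in = d.d_mol + d.d_comp + d.d_type;
  if (d.d_token % d.n_heads != 0) stop("d_token must be divisible by n_heads");
  d.dk = d.d_token / d.n_heads;
  return d;
}

struct BlockOff {
  int ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
      ln2_g, ln2_b, Wm1, bm1, Wm2, bm2;
};
struct TaskOff { int cls, hW1, hb1, hW2, hb2; };
struct Off {
  int gc_mu, gc_ls, gn_mu, gn_ls, type_emb, phase_emb,
      c_W1, c_b1, c_W2, c_b2, lnf_g, lnf_b;
  std::vector<BlockOff> blk;
  std::vector<TaskOff> task;
};

static Off read_layout(const List& layout, const Dims& d) {
  Off o;
  o.gc_mu = layout["gc_mu"]; o.gc_ls = layout["gc_ls"];
  o.gn_mu = layout["gn_mu"]; o.gn_ls = layout["gn_ls"];
  o.type_emb = layout["type_emb"]; o.phase_emb = layout["phase_emb"];
  o.c_W1 = layout["c_W1"]; o.c_b1 = layout["c_b1"];
  o.c_W2 = layout["c_W2"]; o.c_b2 = layout["c_b2"];
  o.lnf_g = layout["lnf_g"]; o.lnf_b = layout["lnf_b"];
  List blks = layout["blocks"];
  for (int b = 0; b < d.n_blocks; ++b) {
    List L = blks[b];
    BlockOff w;
    w.ln1_g = L["ln1_g"]; w.ln1_b = L["ln1_b"];
    w.Wq = L["Wq"]; w.bq = L["bq"]; w.Wk = L["Wk"]; w.bk = L["bk"];
    w.Wv = L["Wv"]; w.bv = L["bv"]; w.Wo = L["Wo"]; w.bo = L["bo"];
    w.ln2_g = L["ln2_g"]; w.ln2_b = L["ln2_b"];
    w.Wm1 = L["Wm1"]; w.bm1 = L["bm1"]; w.Wm2 = L["Wm2"]; w.bm2 = L["bm2"];
    o.blk.push_back(w);
  }
  List tsk = layout["tasks"];
  for (int t = 0; t < d.n_tasks; ++t) {
    List L = tsk[t];
    TaskOff w;
    w.cls = L["cls"]; w.hW1 = L["hW1"]; w.hb1 = L["hb1"];
    w.hW2 = L["hW2"]; w.hb2 = L["hb2"];
    o.task.push_back(w);
  }
  return o;
}

// in-place view constructors (no copy; writes alias the flat vector)
#define PMAT(base, off, r, c) mat(base + (off), (r), (c), false, true)
#define PVEC(base, off, n) vec(base + (off), (n), false, true)

// ---- layernorm (rowwise) --------------------------------------------------

struct LNCache { mat xhat; vec inv_std; };

static mat layernorm_fwd(const mat& X, const vec& g, const vec& b, LNCache& c) {
  const int R = X.n_rows, D = X.n_cols;
  c.xhat.set_size(R, D); c.inv_std.set_size(R);
  mat Y(R, D);
  rowvec gt = g.t(), bt = b.t();
  for (int r = 0; r < R; ++r) {
    rowvec x = X.row(r);
    double mu = arma::mean(x);
    rowvec xc = x - mu;
    double v = arma::dot(xc, xc) / D;
    double is = 1.0 / std::sqrt(v + LN_EPS);
    c.inv_std(r) = is;
    c.xhat.row(r) = xc * is;
    Y.row(r) = c.xhat.row(r) % gt + bt;
  }
  return Y;
}

static mat layernorm_bwd(const mat& dY, const vec& g, const LNCache& c,
                         vec&& dg, vec&& db) {
  const int R = dY.n_rows, D = dY.n_cols;
  mat dX(R, D);
  rowvec gt = g.t();
  for (int r = 0; r < R; ++r) {
    rowvec dy = dY.row(r);
    rowvec xh = c.xhat.row(r);
    dg += (dy % xh).t();
    db += dy.t();
    rowvec dxh = dy % gt;
    double m1 = arma::mean(dxh);
    double m2 = arma::mean(dxh % xh);
    dX.row(r) = (dxh - m1 - xh * m2) * c.inv_std(r);
  }
  return dX;
}

// ---- caches ---------------------------------------------------------------

struct BlockCache {
  LNCache ln1, ln2;
  mat Xn1, Q, K, V, O, Xn2, M1;
  std::vector<mat> A; // per formulation: L x (L * n_heads)
};

struct Cache {
  mat E, H1, Ctok, Gnp;
  std::vector<BlockCache> blk;
  LNCache lnf;
  mat Xf;
  mat U; // head hidden (post relu), n_form x hh
  arma::ivec row0, Lr;
};

static inline rowvec gauss_enc(double v, const vec& mu, const vec& ls) {
  vec sg = arma::exp(ls);
  vec z = (v - mu) / sg;
  return arma::exp(-0.5 * arma::square(z)).t();
}

// ---- forward --------------------------------------------------------------

// Builds the token matrix and runs the blocks; returns scores for task t.
// Raw-feature inputs (FP/molar/type/np/phase) are used unless Ein is given
// (embedding-level path for attribution).
static vec core_forward(const double* pb, const Off& o, const Dims& d,
                        const mat* FP, const vec* molar,
                        const arma::ivec* type, const arma::ivec& ncomp,
                        const vec* np, const arma::ivec* phase,
                        const mat* Ein, const mat* Enp_in,
                        const mat* Ephase_in, int t, Cache& c) {
  double* pbm = const_cast<double*>(pb);
  const int n_form = ncomp.n_elem;
  const int Lfix = 2 + d.n_tasks;
  const int n_comp_total = arma::sum(ncomp);
  const int R = n_comp_total + n_form * Lfix;

  const vec gc_mu = PVEC(pbm, o.gc_mu, d.d_comp);
  const vec gc_ls = PVEC(pbm, o.gc_ls, d.d_comp);
  const vec gn_mu = PVEC(pbm, o.gn_mu, d.d_token);
  const vec gn_ls = PVEC(pbm, o.gn_ls, d.d_token);
  const mat type_emb = PMAT(pbm, o.type_emb, d.d_type, d.n_types);
  const mat phase_emb = PMAT(pbm, o.phase_emb, d.d_token, d.n_phases);
  const mat c_W1 = PMAT(pbm, o.c_W1, d.d_in, d.d_token);
  const vec c_b1 = PVEC(pbm, o.c_b1, d.d_token);
  const mat c_W2 = PMAT(pbm, o.c_W2, d.d_token, d.d_token);
  const vec c_b2 = PVEC(pbm, o.c_b2, d.d_token);

  if (Ein) {
    c.E = *Ein;
  } else {
    c.E.set_size(n_comp_total, d.d_in);
    for (int k = 0; k < n_comp_total; ++k) {
      c.E(k, arma::span(0, d.d_mol - 1)) = FP->col(k).t();
      c.E(k, arma::span(d.d_mol, d.d_mol + d.d_comp - 1)) =
        gauss_enc((*molar)(k), gc_mu, gc_ls);
      c.E(k, arma::span(d.d_mol + d.d_comp, d.d_in - 1)) =
        type_emb.col((*type)(k)).t();
    }
  }
  c.H1 = c.E * c_W1;
  c.H1.each_row() += c_b1.t();
  c.H1.transform([](double x){ return x > 0 ? x : 0.0; });
  c.Ctok = c.H1 * c_W2;
  c.Ctok.each_row() += c_b2.t();

  if (Enp_in) c.Gnp = *Enp_in;
  else {
    c.Gnp.set_size(n_form, d.d_token);
    for (int i = 0; i < n_form; ++i)
      c.Gnp.row(i) = gauss_enc((*np)(i), gn_mu, gn_ls);
  }
  mat Eph;
  if (Ephase_in) Eph = *Ephase_in;
  else {
    Eph.set_size(n_form, d.d_token);
    for (int i = 0; i < n_form; ++i)
      Eph.row(i) = phase_emb.col((*phase)(i)).t();
  }

  mat X(R, d.d_token);
  c.row0.set_size(n_form); c.Lr.set_size(n_form);
  {
    int r = 0, k0 = 0;
    for (int i = 0; i < n_form; ++i) {
      int ni = ncomp(i);
      c.row0(i) = r; c.Lr(i) = ni + Lfix;
      X.rows(r, r + ni - 1) = c.Ctok.rows(k0, k0 + ni - 1);
      X.row(r + ni) = c.Gnp.row(i);
      X.row(r + ni + 1) = Eph.row(i);
      for (int tt = 0; tt < d.n_tasks; ++tt)
        X.row(r + ni + 2 + tt) = PVEC(pbm, o.task[tt].cls, d.d_token).t();
      r += ni + Lfix; k0 += ni;
    }
  }

  c.blk.resize(d.n_blocks);
  const double sc = 1.0 / std::sqrt((double) d.dk);
  for (int b = 0; b < d.n_blocks; ++b) {
    BlockCache& bc = c.blk[b];
    const BlockOff& w = o.blk[b];
    bc.Xn1 = layernorm_fwd(X, PVEC(pbm, w.ln1_g, d.d_token),
                           PVEC(pbm, w.ln1_b, d.d_token), bc.ln1);
    bc.Q = bc.Xn1 * PMAT(pbm, w.Wq, d.d_token, d.d_token);
    bc.Q.each_row() += PVEC(pbm, w.bq, d.d_token).t();
    bc.K = bc.Xn1 * PMAT(pbm, w.Wk, d.d_token, d.d_token);
    bc.K.each_row() += PVEC(pbm, w.bk, d.d_token).t();
    bc.V = bc.Xn1 * PMAT(pbm, w.Wv, d.d_token, d.d_token);
    bc.V.each_row() += PVEC(pbm, w.bv, d.d_token).t();
    bc.O.set_size(R, d.d_token);
    bc.A.assign(n_form, mat());
    for (int i = 0; i < n_form; ++i) {
      int rr = c.row0(i), L = c.Lr(i);
      bc.A[i].set_size(L, L * d.n_heads);
      arma::span rs(rr, rr + L - 1);
      for (int h = 0; h < d.n_heads; ++h) {
        arma::span cs(h * d.dk, (h + 1) * d.dk - 1);
        mat S = bc.Q(rs, cs) * bc.K(rs, cs).t() * sc;
        for (int q = 0; q < L; ++q) {
          rowvec s = S.row(q);
          s -= s.max();
          s = arma::exp(s);
          S.row(q) = s / arma::accu(s);
        }
        bc.A[i].cols(h * L, (h + 1) * L - 1) = S;
        bc.O(rs, cs) = S * bc.V(rs, cs);
      }
    }
    mat attn = bc.O * PMAT(pbm, w.Wo, d.d_token, d.d_token);
    attn.each_row() += PVEC(pbm, w.bo, d.d_token).t();
    X += attn;
    bc.Xn2 = layernorm_fwd(X, PVEC(pbm, w.ln2_g, d.d_token),
                           PVEC(pbm, w.ln2_b, d.d_token), bc.ln2);
    bc.M1 = bc.Xn2 * PMAT(pbm, w.Wm1, d.d_token, d.mlp);
    bc.M1.each_row() += PVEC(pbm, w.bm1, d.mlp).t();
    bc.M1.transform([](double x){ return x > 0 ? x : 0.0; });
    mat M2 = bc.M1 * PMAT(pbm, w.Wm2, d.mlp, d.d_token);
    M2.each_row() += PVEC(pbm, w.bm2, d.d_token).t();
    X += M2;
  }
  c.Xf = layernorm_fwd(X, PVEC(pbm, o.lnf_g, d.d_token),
                       PVEC(pbm, o.lnf_b, d.d_token), c.lnf);

  const TaskOff& tw = o.task[t];
  const mat hW1 = PMAT(pbm, tw.hW1, d.d_token, d.hh);
  const vec hb1 = PVEC(pbm, tw.hb1, d.hh);
  const vec hW2 = PVEC(pbm, tw.hW2, d.hh);
  const double hb2 = pb[tw.hb2];
  vec scores(n_form);
  c.U.set_size(n_form, d.hh);
  for (int i = 0; i < n_form; ++i) {
    int cls_r = c.row0(i) + ncomp(i) + 2 + t;
    rowvec u = c.Xf.row(cls_r) * hW1 + hb1.t();
    u.transform([](double x){ return x > 0 ? x : 0.0; });
    c.U.row(i) = u;
    scores(i) = arma::dot(u.t(), hW2) + hb2;
  }
  return scores;
}

// ---- backward -------------------------------------------------------------

// ds: dLoss/dscore per formulation. Parameter gradients are accumulated
// in place into gb (same layout as the parameter vector). Embedding-level
// input gradients are returned when the *_out pointers are non-null.
static void core_backward(const double* pb, double* gb, const Off& o,
                          const Dims& d, const Cache& c,
                          const arma::ivec& ncomp,
                          const vec* molar, const arma::ivec* type,
                          const arma::ivec* phase, const vec* np,
                          int t, const vec& ds,
                          mat* dE_out, mat* dEnp_out, mat* dEphase_out) {
  double* pbm = const_cast<double*>(pb);
  const int n_form = ncomp.n_elem;
  const int R = c.Xf.n_rows;
  const double sc = 1.0 / std::sqrt((double) d.dk);

  // prediction head
  mat dXf(R, d.d_token, arma::fill::zeros);
  {
    const TaskOff& tw = o.task[t];
    const mat hW1 = PMAT(pbm, tw.hW1, d.d_token, d.hh);
    const vec hW2 = PVEC(pbm, tw.hW2, d.hh);
    for (int i = 0; i < n_form; ++i) {
      if (ds(i) == 0.0) continue;
      int cls_r = c.row0(i) + ncomp(i) + 2 + t;
      rowvec u = c.U.row(i);
      PVEC(gb, tw.hW2, d.hh) += ds(i) * u.t();
      gb[tw.hb2] += ds(i);
      rowvec dz = ds(i) * hW2.t();
      for (int j = 0; j < d.hh; ++j) if (u(j) <= 0.0) dz(j) = 0.0;
      PMAT(gb, tw.hW1, d.d_token, d.hh) += c.Xf.row(cls_r).t() * dz;
      PVEC(gb, tw.hb1, d.hh) += dz.t();
      dXf.row(cls_r) += dz * hW1.t();
    }
  }

  mat dX = layernorm_bwd(dXf, PVEC(pbm, o.lnf_g, d.d_token), c.lnf,
                         PVEC(gb, o.lnf_g, d.d_token),
                         PVEC(gb, o.lnf_b, d.d_token));

  for (int b = d.n_blocks - 1; b >= 0; --b) {
    const BlockCache& bc = c.blk[b];
    const BlockOff& w = o.blk[b];
    // MLP sublayer
    mat dM1 = dX * PMAT(pbm, w.Wm2, d.mlp, d.d_token).t();
    PMAT(gb, w.Wm2, d.mlp, d.d_token) += bc.M1.t() * dX;
    PVEC(gb, w.bm2, d.d_token) += arma::sum(dX, 0).t();
    dM1 %= arma::conv_to<mat>::from(bc.M1 > 0);
    mat dXn2 = dM1 * PMAT(pbm, w.Wm1, d.d_token, d.mlp).t();
    PMAT(gb, w.Wm1, d.d_token, d.mlp) += bc.Xn2.t() * dM1;
    PVEC(gb, w.bm1, d.mlp) += arma::sum(dM1, 0).t();
    dX += layernorm_bwd(dXn2, PVEC(pbm, w.ln2_g, d.d_token), bc.ln2,
                        PVEC(gb, w.ln2_g, d.d_token),
                        PVEC(gb, w.ln2_b, d.d_token));
    // attention sublayer
    mat dO = dX * PMAT(pbm, w.Wo, d.d_token, d.d_token).t();
    PMAT(gb, w.Wo, d.d_token, d.d_token) += bc.O.t() * dX;
    PVEC(gb, w.bo, d.d_token) += arma::sum(dX, 0).t();
    mat dQ(R, d.d_token, arma::fill::zeros);
    mat dK(R, d.d_token, arma::fill::zeros);
    mat dV(R, d.d_token, arma::fill::zeros);
    for (int i = 0; i < n_form; ++i) {
      int rr = c.row0(i), L = c.Lr(i);
      arma::span rs(rr, rr + L - 1);
      for (int h = 0; h < d.n_heads; ++h) {
        arma::span csp(h * d.dk, (h + 1) * d.dk - 1);
        mat A = bc.A[i].cols(h * L, (h + 1) * L - 1);
        mat dOh = dO(rs, csp);
        mat dA = dOh * bc.V(rs, csp).t();
        dV(rs, csp) += A.t() * dOh;
        mat dS(L, L);
        for (int q = 0; q < L; ++q) {
          rowvec a = A.row(q);
          rowvec da = dA.row(q);
          dS.row(q) = a % (da - arma::dot(a, da));
        }
        dQ(rs, csp) += dS * bc.K(rs, csp) * sc;
        dK(rs, csp) += dS.t() * bc.Q(rs, csp) * sc;
      }
    }
    PMAT(gb, w.Wq, d.d_token, d.d_token) += bc.Xn1.t() * dQ;
    PVEC(gb, w.bq, d.d_token) += arma::sum(dQ, 0).t();
    PMAT(gb, w.Wk, d.d_token, d.d_token) += bc.Xn1.t() * dK;
    PVEC(gb, w.bk, d.d_token) += arma::sum(dK, 0).t();
    PMAT(gb, w.Wv, d.d_token, d.d_token) += bc.Xn1.t() * dV;
    PVEC(gb, w.bv, d.d_token) += arma::sum(dV, 0).t();
    mat dXn1 = dQ * PMAT(pbm, w.Wq, d.d_token, d.d_token).t() +
               dK * PMAT(pbm, w.Wk, d.d_token, d.d_token).t() +
               dV * PMAT(pbm, w.Wv, d.d_token, d.d_token).t();
    dX += layernorm_bwd(dXn1, PVEC(pbm, w.ln1_g, d.d_token), bc.ln1,
                        PVEC(gb, w.ln1_g, d.d_token),
                        PVEC(gb, w.ln1_b, d.d_token));
  }

  // scatter dX back to token sources
  const int n_comp_total = c.E.n_rows;
  mat dCtok(n_comp_total, d.d_token);
  mat dGnp(n_form, d.d_token), dPh(n_form, d.d_token);
  {
    int k0 = 0;
    for (int i = 0; i < n_form; ++i) {
      int rr = c.row0(i), ni = ncomp(i);
      dCtok.rows(k0, k0 + ni - 1) = dX.rows(rr, rr + ni - 1);
      dGnp.row(i) = dX.row(rr + ni);
      dPh.row(i) = dX.row(rr + ni + 1);
      for (int tt = 0; tt < d.n_tasks; ++tt)
        PVEC(gb, o.task[tt].cls, d.d_token) += dX.row(rr + ni + 2 + tt).t();
      k0 += ni;
    }
  }

  // component MLP
  mat dH1 = dCtok * PMAT(pbm, o.c_W2, d.d_token, d.d_token).t();
  PMAT(gb, o.c_W2, d.d_token, d.d_token) += c.H1.t() * dCtok;
  PVEC(gb, o.c_b2, d.d_token) += arma::sum(dCtok, 0).t();
  dH1 %= arma::conv_to<mat>::from(c.H1 > 0);
  mat dEmat = dH1 * PMAT(pbm, o.c_W1, d.d_in, d.d_token).t();
  PMAT(gb, o.c_W1, d.d_in, d.d_token) += c.E.t() * dH1;
  PVEC(gb, o.c_b1, d.d_token) += arma::sum(dH1, 0).t();

  if (dE_out) *dE_out = dEmat;
  if (dEnp_out) *dEnp_out = dGnp;
  if (dEphase_out) *dEphase_out = dPh;

  if (molar) {
    const vec gc_mu = PVEC(pbm, o.gc_mu, d.d_comp);
    const vec sg = arma::exp(PVEC(pbm, o.gc_ls, d.d_comp));
    for (int k = 0; k < n_comp_total; ++k) {
      vec de = dEmat(k, arma::span(d.d_mol, d.d_mol + d.d_comp - 1)).t();
      vec e = c.E(k, arma::span(d.d_mol, d.d_mol + d.d_comp - 1)).t();
      vec diff = (*molar)(k) - gc_mu;
      PVEC(gb, o.gc_mu, d.d_comp) += (e % de) % (diff / arma::square(sg));
      PVEC(gb, o.gc_ls, d.d_comp) +=
        (e % de) % (arma::square(diff) / arma::square(sg));
      PMAT(gb, o.type_emb, d.d_type, d.n_types).col((*type)(k)) +=
        dEmat(k, arma::span(d.d_mol + d.d_comp, d.d_in - 1)).t();
    }
  }
  if (np) {
    const vec gn_mu = PVEC(pbm, o.gn_mu, d.d_token);
    const vec sg = arma::exp(PVEC(pbm, o.gn_ls, d.d_token));
    for (int i = 0; i < n_form; ++i) {
      vec e = c.Gnp.row(i).t();
      vec de = dGnp.row(i).t();
      vec diff = (*np)(i) - gn_mu;
      PVEC(gb, o.gn_mu, d.d_token) += (e % de) % (diff / arma::square(sg));
      PVEC(gb, o.gn_ls, d.d_token) +=
        (e % de) % (arma::square(diff) / arma::square(sg));
    }
  }
  if (phase) {
    for (int i = 0; i < n_form; ++i)
      PMAT(gb, o.phase_emb, d.d_token, d.n_phases).col((*phase)(i)) +=
        dPh.row(i).t();
  }
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
List cpp_comet_scores(NumericVector theta, List cfg, List layout,
                      NumericMatrix FP, NumericVector molar,
                      IntegerVector type, IntegerVector ncomp,
                      NumericVector np, IntegerVector phase,
                      int task_idx, bool want_cls) {
  Dims d = read_dims(cfg);
  Off o = read_layout(layout, d);
  mat fp(FP.begin(), FP.nrow(), FP.ncol(), false);
  vec mol(molar.begin(), molar.size(), false);
  arma::ivec ty = as<arma::ivec>(type), nc = as<arma::ivec>(ncomp),
             ph = as<arma::ivec>(phase);
  vec npv(np.begin(), np.size(), false);
  Cache c;
  vec s = core_forward(REAL(theta), o, d, &fp, &mol, &ty, nc, &npv, &ph,
                       nullptr, nullptr, nullptr, task_idx, c);
  List out = List::create(Named("scores") = NumericVector(s.begin(), s.end()));
  if (want_cls) {
    mat cls(nc.n_elem, d.d_token);
    for (arma::uword i = 0; i < nc.n_elem; ++i)
      cls.row(i) = c.Xf.row(c.row0(i) + nc(i) + 2 + task_idx);
    out["cls"] = wrap(cls);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_comet_rank_grad(NumericVector theta, NumericVector grad,
                         List cfg, List layout,
                         NumericMatrix FP, NumericVector molar,
                         IntegerVector type, IntegerVector ncomp,
                         NumericVector np, IntegerVector phase,
                         int task_idx,
                         IntegerVector pair_h, IntegerVector pair_l,
                         NumericVector dy, double lambda) {
  Dims d = read_dims(cfg);
  Off o = read_layout(layout, d);
  mat fp(FP.begin(), FP.nrow(), FP.ncol(), false);
  vec mol(molar.begin(), molar.size(), false);
  arma::ivec ty = as<arma::ivec>(type), nc = as<arma::ivec>(ncomp),
             ph = as<arma::ivec>(phase);
  vec npv(np.begin(), np.size(), false);
  Cache c;
  vec s = core_forward(REAL(theta), o, d, &fp, &mol, &ty, nc, &npv, &ph,
                       nullptr, nullptr, nullptr, task_idx, c);
  const int P = pair_h.size();
  vec ds(nc.n_elem, arma::fill::zeros);
  double loss = 0.0;
  for (int j = 0; j < P; ++j) {
    int ih = pair_h[j], il = pair_l[j];
    double m = s(ih) - s(il) - lambda * dy[j];
    loss += std::max(-m, 0.0) + std::log1p(std::exp(-std::abs(m)));
    double g = -1.0 / (1.0 + std::exp(m)); // d loss / d m = -sigmoid(-m)
    ds(ih) += g / P;
    ds(il) -= g / P;
  }
  loss /= P;
  core_backward(REAL(theta), REAL(grad), o, d, c, nc, &mol, &ty, &ph, &npv,
                task_idx, ds, nullptr, nullptr, nullptr);
  return List::create(Named("loss") = loss,
                      Named("scores") = NumericVector(s.begin(), s.end()));
}

// [[Rcpp::export]]
List cpp_comet_reg_grad(NumericVector theta, NumericVector grad,
                        List cfg, List layout,
                        NumericMatrix FP, NumericVector molar,
                        IntegerVector type, IntegerVector ncomp,
                        NumericVector np, IntegerVector phase,
                        int task_idx, NumericVector y) {
  Dims d = read_dims(cfg);
  Off o = read_layout(layout, d);
  mat fp(FP.begin(), FP.nrow(), FP.ncol(), false);
  vec mol(molar.begin(), molar.size(), false);
  arma::ivec ty = as<arma::ivec>(type), nc = as<arma::ivec>(ncomp),
             ph = as<arma::ivec>(phase);
  vec npv(np.begin(), np.size(), false);
  Cache c;
  vec s = core_forward(REAL(theta), o, d, &fp, &mol, &ty, nc, &npv, &ph,
                       nullptr, nullptr, nullptr, task_idx, c);
  const int n = s.n_elem;
  vec yv(y.begin(), n, false);
  vec r = s - yv;
  double loss = arma::dot(r, r) / n;
  vec ds = 2.0 * r / n;
  core_backward(REAL(theta), REAL(grad), o, d, c, nc, &mol, &ty, &ph, &npv,
                task_idx, ds, nullptr, nullptr, nullptr);
  return List::create(Named("loss") = loss,
                      Named("scores") = NumericVector(s.begin(), s.end()));
}

// Embedding-level score and input gradients for one formulation (the
// integrated-gradients path). Ecomp: n_comp x d_in; enp, ephase: d_token.
// [[Rcpp::export]]
List cpp_comet_embed_score(NumericVector theta, List cfg, List layout,
                           NumericMatrix Ecomp, NumericVector enp,
                           NumericVector ephase, int task_idx,
                           bool want_grad) {
  Dims d = read_dims(cfg);
  Off o = read_layout(layout, d);
  mat E(Ecomp.begin(), Ecomp.nrow(), Ecomp.ncol(), false);
  mat Enp(1, d.d_token), Eph(1, d.d_token);
  Enp.row(0) = vec(enp.begin(), d.d_token, false).t();
  Eph.row(0) = vec(ephase.begin(), d.d_token, false).t();
  arma::ivec nc(1); nc(0) = E.n_rows;
  Cache c;
  vec s = core_forward(REAL(theta), o, d, nullptr, nullptr, nullptr, nc,
                       nullptr, nullptr, &E, &Enp, &Eph, task_idx, c);
  List out = List::create(Named("score") = s(0));
  if (want_grad) {
    NumericVector scratch(theta.size()); // param grads discarded
    vec ds(1); ds(0) = 1.0;
    mat dE, dEnp, dEph;
    core_backward(REAL(theta), REAL(scratch), o, d, c, nc, nullptr, nullptr,
                  nullptr, nullptr, task_idx, ds, &dE, &dEnp, &dEph);
    out["dEcomp"] = wrap(dE);
    out["dEnp"] = NumericVector(dEnp.begin(), dEnp.end());
    out["dEphase"] = NumericVector(dEph.begin(), dEph.end());
  }
  return out;
}
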