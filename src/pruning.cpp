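// Pruning-algorithm likelihood core for 20-state amino-acid models.
//
// Trees arrive as ape-style postorder edge matrices (0-based here), tip
// states as an integer matrix (pattern x tip) with codes 0..19 and NS (=20)
// for gap/unknown (fully ambiguous).  The reversible substitution model is
// passed in eigendecomposed form: P(t) = V diag(exp(lambda * r * t)) Vinv,
// with stationary frequencies pi and per-category rates r (equal weights).
//
// Per-pattern scaling (log accumulators) guards against underflow; the
// scale is shared across rate categories so the category average stays
// exact.  Inner kernels iterate the transition matrix by columns so the
// compiler can vectorize contiguous runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NS = 20;

struct Model {
  std::vector<double> lambda, V, Vinv, pi, rates;
  int ncat;
};

static Model make_model(const NumericVector &lambda, const NumericMatrix &V,
                        const NumericMatrix &Vinv, const NumericVector &pi,
                        const NumericVector &rates) {
  Model m;
  m.lambda.assign(lambda.begin(), lambda.end());
  m.V.assign(V.begin(), V.end());       // column-major 20x20
  m.Vinv.assign(Vinv.begin(), Vinv.end());
  m.pi.assign(pi.begin(), pi.end());
  m.rates.assign(rates.begin(), rates.end());
  m.ncat = rates.size();
  return m;
}

// P(t) for one category rate r, column-major 20x20, plus row sums.
static void pmat(const Model &m, double t, double r, double *P,
                 double *rowsum) {
  double ex[NS];
  for (int k = 0; k < NS; ++k) ex[k] = std::exp(m.lambda[k] * r * t);
  for (int j = 0; j < NS; ++j) {
    double *Pj = P + NS * j;
    for (int i = 0; i < NS; ++i) Pj[i] = 0.0;
    for (int k = 0; k < NS; ++k) {
      double w = ex[k] * m.Vinv[k + NS * j];
      const double *Vk = &m.V[NS * k];
      for (int i = 0; i < NS; ++i) Pj[i] += Vk[i] * w;
    }
    for (int i = 0; i < NS; ++i) if (Pj[i] < 0.0) Pj[i] = 0.0;
  }
  for (int i = 0; i < NS; ++i) rowsum[i] = 0.0;
  for (int j = 0; j < NS; ++j) {
    const double *Pj = P + NS * j;
    for (int i = 0; i < NS; ++i) rowsum[i] += Pj[i];
  }
}

// out[i] = sum_j P[i,j] in[j]  (column-major P, contiguous in i)
static inline void contract(const double *P, const double *in, double *out) {
  for (int i = 0; i < NS; ++i) out[i] = 0.0;
  for (int j = 0; j < NS; ++j) {
    double c = in[j];
    if (c == 0.0) continue;
    const double *Pj = P + NS * j;
    for (int i = 0; i < NS; ++i) out[i] += Pj[i] * c;
  }
}

struct TreeData {
  std::vector<int> par, ch;     // postorder edges
  int nedge, ntip, nnode, npat, root;
  std::vector<int> tip;         // tipstate, column-major [tipidx][pat]
};

static TreeData make_tree(const IntegerMatrix &edge, int ntip,
                          int nnode_total, const IntegerMatrix &tipstate) {
  TreeData td;
  td.nedge = edge.nrow();
  td.ntip = ntip;
  td.nnode = nnode_total;
  td.npat = tipstate.nrow();
  td.par.resize(td.nedge);
  td.ch.resize(td.nedge);
  for (int e = 0; e < td.nedge; ++e) {
    td.par[e] = edge(e, 0);
    td.ch[e] = edge(e, 1);
  }
  td.root = td.par[td.nedge - 1];
  td.tip.resize((size_t)ntip * td.npat);
  for (int j = 0; j < ntip; ++j)
    for (int s = 0; s < td.npat; ++s)
      td.tip[(size_t)j * td.npat + s] = tipstate(s, j);
  return td;
}

// multiply the message of edge e (length t) into dest[cat][pat][NS]
static void apply_edge(const TreeData &td, const Model &m, int e, double t,
                       const double *childpartial /* or NULL for tip */,
                       double *dest) {
  const int npat = td.npat;
  static std::vector<double> P(NS * NS), rowsum(NS), tmp(NS);
  int ch = td.ch[e];
  for (int c = 0; c < m.ncat; ++c) {
    pmat(m, t, m.rates[c], P.data(), rowsum.data());
    double *dc = dest + (size_t)c * npat * NS;
    if (childpartial == nullptr) {
      const int *ts = &td.tip[(size_t)ch * npat];
      for (int s = 0; s < npat; ++s) {
        double *out = dc + (size_t)s * NS;
        int st = ts[s];
        if (st >= 0 && st < NS) {
          const double *Pj = &P[NS * st];
          for (int i = 0; i < NS; ++i) out[i] *= Pj[i];
        } else {
          for (int i = 0; i < NS; ++i) out[i] *= rowsum[i];
        }
      }
    } else {
      const double *cp = childpartial + (size_t)c * npat * NS;
      for (int s = 0; s < npat; ++s) {
        contract(P.data(), cp + (size_t)s * NS, tmp.data());
        double *out = dc + (size_t)s * NS;
        for (int i = 0; i < NS; ++i) out[i] *= tmp[i];
      }
    }
  }
}

// down-partials for internal nodes; partial laid out [node][cat][pat][NS]
static void down_pass(const TreeData &td, const Model &m,
                      const std::vector<double> &elen,
                      std::vector<double> &partial,
                      std::vector<double> &scalelog) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  partial.assign((size_t)td.nnode * stride, 0.0);
  scalelog.assign((size_t)td.nnode * npat, 0.0);
  std::vector<char> touched(td.nnode, 0);
  for (int e = 0; e < td.nedge; ++e) {
    int par = td.par[e], ch = td.ch[e];
    double *pp = &partial[(size_t)par * stride];
    double *sp = &scalelog[(size_t)par * npat];
    if (!touched[par]) {
      std::fill(pp, pp + stride, 1.0);
      std::fill(sp, sp + npat, 0.0);
      touched[par] = 1;
    }
    apply_edge(td, m, e, elen[e],
               ch < td.ntip ? nullptr : &partial[(size_t)ch * stride], pp);
    if (ch >= td.ntip) {
      const double *cs = &scalelog[(size_t)ch * npat];
      for (int s = 0; s < npat; ++s) sp[s] += cs[s];
    }
    for (int s = 0; s < npat; ++s) {
      double mx = 0.0;
      for (int c = 0; c < m.ncat; ++c) {
        const double *pc = pp + (size_t)c * npat * NS + (size_t)s * NS;
        for (int i = 0; i < NS; ++i) if (pc[i] > mx) mx = pc[i];
      }
      if (mx > 0.0 && (mx < 1e-80 || mx > 1e80)) {
        double inv = 1.0 / mx;
        for (int c = 0; c < m.ncat; ++c) {
          double *pc = pp + (size_t)c * npat * NS + (size_t)s * NS;
          for (int i = 0; i < NS; ++i) pc[i] *= inv;
        }
        sp[s] += std::log(mx);
      }
    }
  }
}

static void root_loglik(const TreeData &td, const Model &m,
                        const std::vector<double> &partial,
                        const std::vector<double> &scalelog, double *out) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  const double *rp = &partial[(size_t)td.root * stride];
  const double *rs = &scalelog[(size_t)td.root * npat];
  for (int s = 0; s < npat; ++s) {
    double lik = 0.0;
    for (int c = 0; c < m.ncat; ++c) {
      const double *pc = rp + (size_t)c * npat * NS + (size_t)s * NS;
      for (int i = 0; i < NS; ++i) lik += m.pi[i] * pc[i];
    }
    lik /= m.ncat;
    out[s] = (lik > 0.0 ? std::log(lik) : R_NegInf) + rs[s];
  }
}

// [[Rcpp::export]]
NumericVector cpp_site_loglik(IntegerMatrix edge, NumericVector elen,
                              int ntip, int nnode_total,
                              IntegerMatrix tipstate, NumericVector lambda,
                              NumericMatrix V, NumericMatrix Vinv,
                              NumericVector pi, NumericVector rates) {
  Model m = make_model(lambda, V, Vinv, pi, rates);
  TreeData td = make_tree(edge, ntip, nnode_total, tipstate);
  std::vector<double> el(elen.begin(), elen.end()), partial, scalelog;
  down_pass(td, m, el, partial, scalelog);
  NumericVector out(td.npat);
  root_loglik(td, m, partial, scalelog, REAL(out));
  return out;
}


// Edge-profile machinery.  For edge e = (p, c), let U be the exclusive
// product at node p (the up-message into p times the messages of p's other
// children) and D the down-partial at c (indicator vectors for a tip).
// The per-pattern likelihood as a function of this edge's length t is
//   a(t) = (1/ncat) sum_cat sum_k W[s, k] exp(lambda_k r_cat t)
// with W[s, k] = (U V)[s, k] * (Vinv D)[k, s].
static void edge_weights(const Model &m, int npat, const double *U,
                         const double *D, std::vector<double> &W) {
  W.assign((size_t)m.ncat * npat * NS, 0.0);
  std::vector<double> VinvT(NS * NS);
  for (int k = 0; k < NS; ++k)
    for (int i = 0; i < NS; ++i)
      VinvT[i + NS * k] = m.Vinv[k + NS * i];
  double uv[NS], vd[NS];
  for (int c = 0; c < m.ncat; ++c) {
    const double *Uc = U + (size_t)c * npat * NS;
    const double *Dc = D + (size_t)c * npat * NS;
    double *Wc = &W[(size_t)c * npat * NS];
    for (int s = 0; s < npat; ++s) {
      const double *u = Uc + (size_t)s * NS;
      const double *d = Dc + (size_t)s * NS;
      for (int k = 0; k < NS; ++k) {
        const double *Vk = &m.V[NS * k];
        const double *Tk = &VinvT[NS * k];
        double au = 0.0, ad = 0.0;
        for (int i = 0; i < NS; ++i) {
          au += u[i] * Vk[i];
          ad += Tk[i] * d[i];
        }
        uv[k] = au;
        vd[k] = ad;
      }
      double *Ws = Wc + (size_t)s * NS;
      for (int k = 0; k < NS; ++k) Ws[k] = uv[k] * vd[k];
    }
  }
}

// value and first two derivatives of sum_s w_s log a_s(t)
static void edge_fval(const Model &m, int npat, const std::vector<double> &W,
                      const double *wts, double t, double *f, double *g,
                      double *h) {
  const int ncat = m.ncat;
  std::vector<double> e((size_t)ncat * NS), le((size_t)ncat * NS);
  for (int c = 0; c < ncat; ++c)
    for (int k = 0; k < NS; ++k) {
      double lr = m.lambda[k] * m.rates[c];
      le[(size_t)c * NS + k] = lr;
      e[(size_t)c * NS + k] = std::exp(lr * t);
    }
  double F = 0.0, G = 0.0, H = 0.0;
  bool bad = false;
  for (int s = 0; s < npat; ++s) {
    double a = 0.0, a1 = 0.0, a2 = 0.0;
    for (int c = 0; c < ncat; ++c) {
      const double *Wc = &W[(size_t)c * npat * NS + (size_t)s * NS];
      const double *ec = &e[(size_t)c * NS];
      const double *lc = &le[(size_t)c * NS];
      for (int k = 0; k < NS; ++k) {
        double v = Wc[k] * ec[k];
        a += v;
        a1 += v * lc[k];
        a2 += v * lc[k] * lc[k];
      }
    }
    if (a <= 0.0) { bad = true; continue; }
    double w = wts[s];
    F += w * std::log(a);
    G += w * a1 / a;
    H += w * (a2 * a - a1 * a1) / (a * a);
  }
  *f = bad ? R_NegInf : F;
  *g = G;
  *h = H;
}

static double optimize_edge(const Model &m, int npat,
                            const std::vector<double> &W, const double *wts,
                            double t0, double tmin, double tmax) {
  double t = t0 < tmin ? tmin : (t0 > tmax ? tmax : t0);
  double f, g, h;
  for (int it = 0; it < 10; ++it) {
    edge_fval(m, npat, W, wts, t, &f, &g, &h);
    if (!R_finite(f)) break;
    double step;
    if (h < -1e-12) step = -g / h;
    else step = (g > 0 ? 0.5 * (t + 1e-3) : -0.5 * t);
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    double tn = t + step;
    if (tn < tmin) tn = tmin;
    if (tn > tmax) tn = tmax;
    double fn, gn, hn;
    edge_fval(m, npat, W, wts, tn, &fn, &gn, &hn);
    int bt = 0;
    while (fn < f && bt < 8 && std::fabs(tn - t) > 1e-12) {
      tn = 0.5 * (tn + t);
      edge_fval(m, npat, W, wts, tn, &fn, &gn, &hn);
      ++bt;
    }
    if (fn < f) break; // no improving step: keep the current length
    if (std::fabs(tn - t) < 1e-9) { t = tn; break; }
    t = tn;
    if (std::fabs(g) < 1e-8) break;
  }
  return t;
}

// down-pass that additionally stores each edge's message (P(t_e) applied
// to the child partial or tip states) so the up-pass and edge profiles can
// reuse them without recomputation
static void down_pass_msgs(const TreeData &td, const Model &m,
                           const std::vector<double> &elen,
                           std::vector<double> &partial,
                           std::vector<double> &scalelog,
                           std::vector<double> &msg) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  partial.assign((size_t)td.nnode * stride, 0.0);
  scalelog.assign((size_t)td.nnode * npat, 0.0);
  msg.assign((size_t)td.nedge * stride, 0.0);
  std::vector<char> touched(td.nnode, 0);
  for (int e = 0; e < td.nedge; ++e) {
    int par = td.par[e], ch = td.ch[e];
    double *pp = &partial[(size_t)par * stride];
    double *sp = &scalelog[(size_t)par * npat];
    if (!touched[par]) {
      std::fill(pp, pp + stride, 1.0);
      std::fill(sp, sp + npat, 0.0);
      touched[par] = 1;
    }
    double *me = &msg[(size_t)e * stride];
    std::fill(me, me + stride, 1.0);
    apply_edge(td, m, e, elen[e],
               ch < td.ntip ? nullptr : &partial[(size_t)ch * stride], me);
    for (size_t i = 0; i < stride; ++i) pp[i] *= me[i];
    if (ch >= td.ntip) {
      const double *cs = &scalelog[(size_t)ch * npat];
      for (int s = 0; s < npat; ++s) sp[s] += cs[s];
    }
    for (int s = 0; s < npat; ++s) {
      double mx = 0.0;
      for (int c = 0; c < m.ncat; ++c) {
        const double *pc = pp + (size_t)c * npat * NS + (size_t)s * NS;
        for (int i = 0; i < NS; ++i) if (pc[i] > mx) mx = pc[i];
      }
      if (mx > 0.0 && (mx < 1e-80 || mx > 1e80)) {
        double inv = 1.0 / mx;
        for (int c = 0; c < m.ncat; ++c) {
          double *pc = pp + (size_t)c * npat * NS + (size_t)s * NS;
          for (int i = 0; i < NS; ++i) pc[i] *= inv;
        }
        sp[s] += std::log(mx);
      }
    }
  }
}

// up-messages anchored at nodes using cached edge messages: upnode[c] =
// P_e^T (upnode[p] * prod of sibling messages), upnode[root] = pi.
// Per-pattern rescaling is allowed (edge profiles only need relative
// values in t).
static void up_nodes_msgs(const TreeData &td, const Model &m,
                          const std::vector<double> &elen,
                          const std::vector<double> &msg,
                          const std::vector<std::vector<int> > &kids,
                          std::vector<double> &upnode) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  upnode.assign((size_t)td.nnode * stride, 0.0);
  {
    double *ur = &upnode[(size_t)td.root * stride];
    for (int c = 0; c < m.ncat; ++c)
      for (int s = 0; s < npat; ++s)
        for (int i = 0; i < NS; ++i)
          ur[(size_t)c * npat * NS + (size_t)s * NS + i] = m.pi[i];
  }
  std::vector<double> tmp(stride), P(NS * NS), rowsum(NS);
  for (int e = td.nedge - 1; e >= 0; --e) {
    int par = td.par[e], ch = td.ch[e];
    if (ch < td.ntip) continue;
    const double *upar = &upnode[(size_t)par * stride];
    std::copy(upar, upar + stride, tmp.begin());
    for (size_t k = 0; k < kids[par].size(); ++k) {
      int es = kids[par][k];
      if (es == e) continue;
      const double *ms = &msg[(size_t)es * stride];
      for (size_t i = 0; i < stride; ++i) tmp[i] *= ms[i];
    }
    double *uc = &upnode[(size_t)ch * stride];
    for (int c = 0; c < m.ncat; ++c) {
      pmat(m, elen[e], m.rates[c], P.data(), rowsum.data());
      const double *tc = &tmp[(size_t)c * npat * NS];
      double *oc = uc + (size_t)c * npat * NS;
      for (int s = 0; s < npat; ++s) {
        const double *in = tc + (size_t)s * NS;
        double *out = oc + (size_t)s * NS;
        for (int j = 0; j < NS; ++j) {
          const double *Pj = &P[NS * j];
          double acc = 0.0;
          for (int i = 0; i < NS; ++i) acc += Pj[i] * in[i];
          out[j] = acc;
        }
      }
    }
    for (int s = 0; s < npat; ++s) {
      double mx = 0.0;
      for (int c = 0; c < m.ncat; ++c) {
        const double *pc = uc + (size_t)c * npat * NS + (size_t)s * NS;
        for (int i = 0; i < NS; ++i) if (pc[i] > mx) mx = pc[i];
      }
      if (mx > 0.0 && (mx < 1e-80 || mx > 1e80)) {
        double inv = 1.0 / mx;
        for (int c = 0; c < m.ncat; ++c) {
          double *pc = uc + (size_t)c * npat * NS + (size_t)s * NS;
          for (int i = 0; i < NS; ++i) pc[i] *= inv;
        }
      }
    }
  }
}

// exclusive product U at the parent of edge e from cached messages, and
// down-partial D at its child (indicators for a tip)
static void build_UD_msgs(const TreeData &td, const Model &m,
                          const std::vector<double> &msg,
                          const std::vector<double> &partial,
                          const std::vector<std::vector<int> > &kids,
                          const std::vector<double> &upnode, int e,
                          std::vector<double> &U, std::vector<double> &D) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  int par = td.par[e], ch = td.ch[e];
  const double *upar = &upnode[(size_t)par * stride];
  std::copy(upar, upar + stride, U.begin());
  for (size_t k = 0; k < kids[par].size(); ++k) {
    int es = kids[par][k];
    if (es == e) continue;
    const double *ms = &msg[(size_t)es * stride];
    for (size_t i = 0; i < stride; ++i) U[i] *= ms[i];
  }
  if (ch >= td.ntip) {
    const double *dc = &partial[(size_t)ch * stride];
    std::copy(dc, dc + stride, D.begin());
  } else {
    std::fill(D.begin(), D.end(), 0.0);
    const int *ts = &td.tip[(size_t)ch * npat];
    for (int c = 0; c < m.ncat; ++c)
      for (int s = 0; s < npat; ++s) {
        double *out = &D[(size_t)c * npat * NS + (size_t)s * NS];
        int st = ts[s];
        if (st >= 0 && st < NS) out[st] = 1.0;
        else for (int i = 0; i < NS; ++i) out[i] = 1.0;
      }
  }
}

// (uncached variants kept for the verification helper)
static void up_nodes(const TreeData &td, const Model &m,
                     const std::vector<double> &elen,
                     const std::vector<double> &partial,
                     const std::vector<std::vector<int> > &kids,
                     std::vector<double> &upnode) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  upnode.assign((size_t)td.nnode * stride, 0.0);
  {
    double *ur = &upnode[(size_t)td.root * stride];
    for (int c = 0; c < m.ncat; ++c)
      for (int s = 0; s < npat; ++s)
        for (int i = 0; i < NS; ++i)
          ur[(size_t)c * npat * NS + (size_t)s * NS + i] = m.pi[i];
  }
  std::vector<double> tmp(stride), P(NS * NS), rowsum(NS);
  for (int e = td.nedge - 1; e >= 0; --e) {
    int par = td.par[e], ch = td.ch[e];
    if (ch < td.ntip) continue;
    const double *upar = &upnode[(size_t)par * stride];
    std::copy(upar, upar + stride, tmp.begin());
    for (size_t k = 0; k < kids[par].size(); ++k) {
      int es = kids[par][k];
      if (es == e) continue;
      int sch = td.ch[es];
      apply_edge(td, m, es, elen[es],
                 sch < td.ntip ? nullptr : &partial[(size_t)sch * stride],
                 tmp.data());
    }
    // transport through edge e: out[j] = sum_i P[i, j] tmp[i]
    double *uc = &upnode[(size_t)ch * stride];
    for (int c = 0; c < m.ncat; ++c) {
      pmat(m, elen[e], m.rates[c], P.data(), rowsum.data());
      const double *tc = &tmp[(size_t)c * npat * NS];
      double *oc = uc + (size_t)c * npat * NS;
      for (int s = 0; s < npat; ++s) {
        const double *in = tc + (size_t)s * NS;
        double *out = oc + (size_t)s * NS;
        for (int j = 0; j < NS; ++j) {
          const double *Pj = &P[NS * j];
          double acc = 0.0;
          for (int i = 0; i < NS; ++i) acc += Pj[i] * in[i];
          out[j] = acc;
        }
      }
    }
    for (int s = 0; s < npat; ++s) {
      double mx = 0.0;
      for (int c = 0; c < m.ncat; ++c) {
        const double *pc = uc + (size_t)c * npat * NS + (size_t)s * NS;
        for (int i = 0; i < NS; ++i) if (pc[i] > mx) mx = pc[i];
      }
      if (mx > 0.0 && (mx < 1e-80 || mx > 1e80)) {
        double inv = 1.0 / mx;
        for (int c = 0; c < m.ncat; ++c) {
          double *pc = uc + (size_t)c * npat * NS + (size_t)s * NS;
          for (int i = 0; i < NS; ++i) pc[i] *= inv;
        }
      }
    }
  }
}

// exclusive product U at the parent of edge e, and down-partial D at its
// child (indicators for a tip)
static void build_UD(const TreeData &td, const Model &m,
                     const std::vector<double> &elen,
                     const std::vector<double> &partial,
                     const std::vector<std::vector<int> > &kids,
                     const std::vector<double> &upnode, int e,
                     std::vector<double> &U, std::vector<double> &D) {
  const int npat = td.npat;
  const size_t stride = (size_t)m.ncat * npat * NS;
  int par = td.par[e], ch = td.ch[e];
  const double *upar = &upnode[(size_t)par * stride];
  std::copy(upar, upar + stride, U.begin());
  for (size_t k = 0; k < kids[par].size(); ++k) {
    int es = kids[par][k];
    if (es == e) continue;
    int sch = td.ch[es];
    apply_edge(td, m, es, elen[es],
               sch < td.ntip ? nullptr : &partial[(size_t)sch * stride],
               U.data());
  }
  if (ch >= td.ntip) {
    const double *dc = &partial[(size_t)ch * stride];
    std::copy(dc, dc + stride, D.begin());
  } else {
    std::fill(D.begin(), D.end(), 0.0);
    const int *ts = &td.tip[(size_t)ch * npat];
    for (int c = 0; c < m.ncat; ++c)
      for (int s = 0; s < npat; ++s) {
        double *out = &D[(size_t)c * npat * NS + (size_t)s * NS];
        int st = ts[s];
        if (st >= 0 && st < NS) out[st] = 1.0;
        else for (int i = 0; i < NS; ++i) out[i] = 1.0;
      }
  }
}

// [[Rcpp::export]]
List cpp_optimize_blens(IntegerMatrix edge, NumericVector elen0, int ntip,
                        int nnode_total, IntegerMatrix tipstate,
                        NumericVector wts, NumericVector lambda,
                        NumericMatrix V, NumericMatrix Vinv, NumericVector pi,
                        NumericVector rates, double tol, int max_pass,
                        double tmin, double tmax, bool allow_fallback) {
  Model m = make_model(lambda, V, Vinv, pi, rates);
  TreeData td = make_tree(edge, ntip, nnode_total, tipstate);
  const int npat = td.npat, nedge = td.nedge;
  const size_t stride = (size_t)m.ncat * npat * NS;
  std::vector<double> elen(elen0.begin(), elen0.end());
  std::vector<double> wv(wts.begin(), wts.end());

  std::vector<double> partial, scalelog, upnode, W, msg;
  std::vector<double> U(stride), D(stride);
  std::vector<double> site(npat);
  std::vector<std::vector<int> > kids(td.nnode);
  for (int e = 0; e < nedge; ++e) kids[td.par[e]].push_back(e);

  double lnL;
  down_pass(td, m, elen, partial, scalelog);
  root_loglik(td, m, partial, scalelog, site.data());
  lnL = 0.0;
  for (int s = 0; s < npat; ++s) lnL += wv[s] * site[s];

  int pass = 0;
  bool converged = false;
  bool sequential = false; // fallback when the joint sweep stalls
  for (pass = 0; pass < max_pass; ++pass) {
    down_pass_msgs(td, m, elen, partial, scalelog, msg);
    up_nodes_msgs(td, m, elen, msg, kids, upnode);
    std::vector<double> newlen(elen);
    for (int e = 0; e < nedge; ++e) {
      build_UD_msgs(td, m, msg, partial, kids, upnode, e, U, D);
      edge_weights(m, npat, U.data(), D.data(), W);
      newlen[e] = optimize_edge(m, npat, W, wv.data(), elen[e], tmin, tmax);
      if (sequential) {
        elen[e] = newlen[e];
        if (e + 1 < nedge) {
          down_pass_msgs(td, m, elen, partial, scalelog, msg);
          up_nodes_msgs(td, m, elen, msg, kids, upnode);
        }
      }
    }

    double lnL_new;
    if (sequential) {
      down_pass(td, m, elen, partial, scalelog);
      root_loglik(td, m, partial, scalelog, site.data());
      lnL_new = 0.0;
      for (int s = 0; s < npat; ++s) lnL_new += wv[s] * site[s];
      double gain = lnL_new - lnL;
      lnL = lnL_new;
      if (gain < tol) { converged = true; ++pass; break; }
      continue;
    }

    // joint sweep: accept with backtracking toward the old lengths
    std::vector<double> trial(newlen);
    int bt = 0;
    for (;;) {
      down_pass(td, m, trial, partial, scalelog);
      root_loglik(td, m, partial, scalelog, site.data());
      lnL_new = 0.0;
      for (int s = 0; s < npat; ++s) lnL_new += wv[s] * site[s];
      if (lnL_new >= lnL - 1e-9 || bt >= 4) break;
      for (int e = 0; e < nedge; ++e) trial[e] = 0.5 * (trial[e] + elen[e]);
      ++bt;
    }
    if (lnL_new < lnL) {
      // stalled: restore and (optionally) fall back to per-edge sweeps
      down_pass(td, m, elen, partial, scalelog);
      if (!allow_fallback) break;
      sequential = true;
      continue;
    }
    double gain = lnL_new - lnL;
    elen = trial;
    lnL = lnL_new;
    if (gain < tol) { converged = true; ++pass; break; }
  }
  return List::create(_["elen"] = NumericVector(elen.begin(), elen.end()),
                      _["loglik"] = lnL, _["converged"] = converged,
                      _["passes"] = pass);
}

// total log-likelihood for many trees sharing one tip set: used by the
// exhaustive-search screening stage (fixed common branch length).
// [[Rcpp::export]]
NumericVector cpp_screen_topologies(List edges, NumericVector nnodes,
                                    double t0, int ntip,
                                    IntegerMatrix tipstate,
                                    NumericVector wts, NumericVector lambda,
                                    NumericMatrix V, NumericMatrix Vinv,
                                    NumericVector pi, NumericVector rates) {
  Model m = make_model(lambda, V, Vinv, pi, rates);
  const int ntree = edges.size();
  NumericVector out(ntree);
  std::vector<double> partial, scalelog, site;
  for (int i = 0; i < ntree; ++i) {
    IntegerMatrix edge = edges[i];
    TreeData td = make_tree(edge, ntip, (int)nnodes[i], tipstate);
    std::vector<double> el(td.nedge, t0);
    down_pass(td, m, el, partial, scalelog);
    site.resize(td.npat);
    root_loglik(td, m, partial, scalelog, site.data());
    double s = 0.0;
    for (int k = 0; k < td.npat; ++k) s += wts[k] * site[k];
    out[i] = s;
  }
  return out;
}

// verification helper: profile log-likelihood of one edge over a length
// grid (constant scale terms dropped; compare differences, not levels)
// [[Rcpp::export]]
NumericVector cpp_edge_profile(IntegerMatrix edge, NumericVector elen0,
                               int ntip, int nnode_total,
                               IntegerMatrix tipstate, NumericVector wts,
                               NumericVector lambda, NumericMatrix V,
                               NumericMatrix Vinv, NumericVector pi,
                               NumericVector rates, int eidx,
                               NumericVector tgrid) {
  Model m = make_model(lambda, V, Vinv, pi, rates);
  TreeData td = make_tree(edge, ntip, nnode_total, tipstate);
  const size_t stride = (size_t)m.ncat * td.npat * NS;
  std::vector<double> elen(elen0.begin(), elen0.end());
  std::vector<double> wv(wts.begin(), wts.end());
  std::vector<double> partial, scalelog, upnode, W;
  std::vector<double> U(stride), D(stride);
  std::vector<std::vector<int> > kids(td.nnode);
  for (int e = 0; e < td.nedge; ++e) kids[td.par[e]].push_back(e);
  down_pass(td, m, elen, partial, scalelog);
  up_nodes(td, m, elen, partial, kids, upnode);
  build_UD(td, m, elen, partial, kids, upnode, eidx, U, D);
  edge_weights(m, td.npat, U.data(), D.data(), W);
  NumericVector out(tgrid.size());
  for (int i = 0; i < tgrid.size(); ++i) {
    double f, g, h;
    edge_fval(m, td.npat, W, wv.data(), tgrid[i], &f, &g, &h);
    out[i] = f;
  }
  return out;
}
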