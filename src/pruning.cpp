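// Pruning-algorithm likelihood for reversible nucleotide models with a
// discrete-gamma + invariant-sites rate mixture, and coordinate-wise
// branch-length optimization on a fixed topology.
//
// Conventions:
//  - edge matrix is in postorder (children listed before their parents),
//    1-based node ids: tips 1..nTip, internals nTip+1..nNode, root passed in.
//  - the rate matrix is supplied eigen-decomposed: Q = U diag(lambda) Uinv,
//    so P(t) = U diag(exp(lambda t)) Uinv.
//  - tip partial likelihoods (4 x npat x nTip) encode ambiguity codes:
//    entry 1 for every compatible state.
//  - `invprod[pat]` = sum_b pi_b * prod_tips tip(b,pat): the invariant-sites
//    mixture weight of a pattern; 0 for any variable pattern.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MINBL = 1e-9;

struct Model {
  double U[16], Uinv[16], lam[4], pi[4];
  std::vector<double> rates; // gamma category rates (already 1/(1-pinv) scaled)
  double pinv;
};

// P(t) = U diag(exp(lambda t)) Uinv, clamped at 0
static inline void pmat(const Model& M, double t, double* P) {
  double e[4];
  for (int i = 0; i < 4; ++i) e[i] = std::exp(M.lam[i] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += M.U[i * 4 + k] * e[k] * M.Uinv[k * 4 + j];
      P[i * 4 + j] = s > 0.0 ? s : 0.0;
    }
}

struct Tree {
  int nTip, nNode, root, nEdge;
  std::vector<int> par, chd;          // per edge, postorder
  std::vector<int> parentOf;          // node -> parent (0 = none)
  std::vector<int> edgeToParent;      // node -> index of edge above it (-1 root)
  std::vector<std::vector<int>> kids; // node -> child edge indices
};

static Tree makeTree(const IntegerMatrix& edge, int nTip, int nNode, int root) {
  Tree T;
  T.nTip = nTip; T.nNode = nNode; T.root = root; T.nEdge = edge.nrow();
  T.par.resize(T.nEdge); T.chd.resize(T.nEdge);
  T.parentOf.assign(nNode + 1, 0);
  T.edgeToParent.assign(nNode + 1, -1);
  T.kids.assign(nNode + 1, {});
  for (int e = 0; e < T.nEdge; ++e) {
    T.par[e] = edge(e, 0); T.chd[e] = edge(e, 1);
    T.parentOf[T.chd[e]] = T.par[e];
    T.edgeToParent[T.chd[e]] = e;
    T.kids[T.par[e]].push_back(e);
  }
  return T;
}

// state code per (pattern, tip): 0..3 for a single compatible state,
// -1 for ambiguity codes (general partial)
static std::vector<int> tipCodes(const double* tip, int nTip, int npat) {
  std::vector<int> code((size_t)nTip * npat, -1);
  for (int n = 0; n < nTip; ++n)
    for (int s = 0; s < npat; ++s) {
      const double* v = tip + ((size_t)n * npat + s) * 4;
      int cnt = 0, last = -1;
      for (int i = 0; i < 4; ++i) if (v[i] == 1.0) { ++cnt; last = i; }
      if (cnt == 1) code[(size_t)n * npat + s] = last;
    }
  return code;
}

// Down (post-order conditional) partials for one rate category.
// part: (4 x npat) per node, flattened (node major); scal: per-pattern log scaler.
static void downPartials(const Tree& T, const Model& M, double rate,
                         const NumericVector& elen, const double* tip,
                         const std::vector<int>& code,
                         int npat, std::vector<double>& part,
                         std::vector<double>& scal) {
  const int stride = 4 * npat;
  // tips (1..nTip) were copied once by the caller; reset internals only
  std::fill(part.begin() + (size_t)(T.nTip + 1) * stride, part.end(), 1.0);
  std::fill(scal.begin(), scal.end(), 0.0);
  double P[16];
  std::vector<int> remaining(T.nNode + 1, 0);
  for (int e = 0; e < T.nEdge; ++e) remaining[T.par[e]]++;
  for (int e = 0; e < T.nEdge; ++e) {
    const int p = T.par[e], c = T.chd[e];
    double t = elen[e]; if (t < MINBL) t = MINBL;
    pmat(M, t * rate, P);
    const double* pc = &part[(size_t)c * stride];
    double* pp = &part[(size_t)p * stride];
    const int* cd = (c <= T.nTip) ? &code[(size_t)(c - 1) * npat] : nullptr;
    for (int s = 0; s < npat; ++s) {
      double* w = pp + 4 * s;
      if (cd && cd[s] >= 0) {
        const int b = cd[s];
        w[0] *= P[b]; w[1] *= P[4 + b]; w[2] *= P[8 + b]; w[3] *= P[12 + b];
        continue;
      }
      const double* v = pc + 4 * s;
      for (int i = 0; i < 4; ++i) {
        double x = P[i * 4 + 0] * v[0] + P[i * 4 + 1] * v[1] +
                   P[i * 4 + 2] * v[2] + P[i * 4 + 3] * v[3];
        w[i] *= x;
      }
    }
    if (--remaining[p] == 0 && p != 0) {
      // node complete: rescale to guard against underflow
      for (int s = 0; s < npat; ++s) {
        double* w = pp + 4 * s;
        double m = std::max(std::max(w[0], w[1]), std::max(w[2], w[3]));
        if (m > 0 && m < 1e-200) {
          for (int i = 0; i < 4; ++i) w[i] /= m;
          scal[s] += std::log(m);
        }
      }
    }
    // propagate child scaler to parent lineage: child scalers already in scal
  }
}

// NOTE on scalers: scal accumulates per pattern over *all* rescaled nodes in
// the category; every node's partial feeds the root exactly once, so the sum
// is the correct total log scaler at the root.

// per-pattern log site likelihood combining categories + invariant sites
static NumericVector patternLogLik(const Tree& T, const Model& M,
                                   const NumericVector& elen, const double* tip,
                                   int npat, const NumericVector& invprod) {
  const int ncat = (int)M.rates.size();
  const int stride = 4 * npat;
  std::vector<int> code = tipCodes(tip, T.nTip, npat);
  std::vector<double> part((size_t)(T.nNode + 1) * stride);
  for (int n = 1; n <= T.nTip; ++n)
    std::copy(tip + (size_t)(n - 1) * stride, tip + (size_t)n * stride,
              part.begin() + (size_t)n * stride);
  std::vector<double> scal(npat);
  NumericMatrix catll(npat, ncat);
  for (int c = 0; c < ncat; ++c) {
    downPartials(T, M, M.rates[c], elen, tip, code, npat, part, scal);
    const double* rootp = &part[(size_t)T.root * stride];
    for (int s = 0; s < npat; ++s) {
      double L = M.pi[0] * rootp[4 * s] + M.pi[1] * rootp[4 * s + 1] +
                 M.pi[2] * rootp[4 * s + 2] + M.pi[3] * rootp[4 * s + 3];
      catll(s, c) = (L > 0 ? std::log(L) : -1e300) + scal[s];
    }
  }
  NumericVector out(npat);
  const double lw = -std::log((double)ncat);
  for (int s = 0; s < npat; ++s) {
    double m = -1e300;
    for (int c = 0; c < ncat; ++c) m = std::max(m, catll(s, c) + lw);
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(catll(s, c) + lw - m);
    double lvar = m + std::log(acc); // log mean over categories
    if (M.pinv > 0.0) {
      double a = std::log1p(-M.pinv) + lvar;
      if (invprod[s] > 0.0) {
        double b = std::log(M.pinv) + std::log(invprod[s]);
        double mm = std::max(a, b);
        out[s] = mm + std::log(std::exp(a - mm) + std::exp(b - mm));
      } else out[s] = a;
    } else out[s] = lvar;
  }
  return out;
}

static Model makeModel(const NumericMatrix& U, const NumericMatrix& Uinv,
                       const NumericVector& lam, const NumericVector& pi,
                       const NumericVector& rates, double pinv) {
  Model M;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      M.U[i * 4 + j] = U(i, j);
      M.Uinv[i * 4 + j] = Uinv(i, j);
    }
  for (int i = 0; i < 4; ++i) { M.lam[i] = lam[i]; M.pi[i] = pi[i]; }
  M.rates.assign(rates.begin(), rates.end());
  M.pinv = pinv;
  return M;
}

// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerMatrix edge, int nTip, int nNode, int root,
                               NumericVector elen, NumericVector tippart, int npat,
                               NumericMatrix U, NumericMatrix Uinv,
                               NumericVector lam, NumericVector pi,
                               NumericVector rates, double pinv,
                               NumericVector invprod) {
  Tree T = makeTree(edge, nTip, nNode, root);
  Model M = makeModel(U, Uinv, lam, pi, rates, pinv);
  return patternLogLik(T, M, elen, REAL(tippart), npat, invprod);
}

// weighted total log-likelihood in one call (hot path for the MCMC)
// [[Rcpp::export]]
double prune_total_cpp(IntegerMatrix edge, int nTip, int nNode, int root,
                       NumericVector elen, NumericVector tippart, int npat,
                       NumericMatrix U, NumericMatrix Uinv,
                       NumericVector lam, NumericVector pi,
                       NumericVector rates, double pinv,
                       NumericVector invprod, NumericVector wts) {
  Tree T = makeTree(edge, nTip, nNode, root);
  Model M = makeModel(U, Uinv, lam, pi, rates, pinv);
  NumericVector ll = patternLogLik(T, M, elen, REAL(tippart), npat, invprod);
  double s = 0.0;
  for (int i = 0; i < npat; ++i) s += wts[i] * ll[i];
  return s;
}

// total log-likelihood with pattern weights
static double totalLogLik(const Tree& T, const Model& M, const NumericVector& elen,
                          const double* tip, int npat, const NumericVector& invprod,
                          const NumericVector& wts) {
  NumericVector ll = patternLogLik(T, M, elen, tip, npat, invprod);
  double s = 0.0;
  for (int i = 0; i < npat; ++i) s += wts[i] * ll[i];
  return s;
}

// Likelihood of the tree as a function of one edge length, all else fixed.
// Precomputes, for edge e = (p, c): F = down partial of c, and A = partial
// of the rest of the tree at p (root prior folded in), per category, with
// per-pattern log scalers. Then lnL(t) is cheap in t.
struct EdgeEnv {
  int npat, ncat;
  bool noscal;                                 // all log scalers exactly 0
  std::vector<std::vector<double>> A, F;       // per cat: 4 x npat
  std::vector<std::vector<double>> sA, sF;     // per cat: npat log scalers
};

static EdgeEnv edgeEnv(const Tree& T, const Model& M, const NumericVector& elen,
                       const double* tip, int npat, int e) {
  const int ncat = (int)M.rates.size();
  const int stride = 4 * npat;
  EdgeEnv E;
  E.npat = npat; E.ncat = ncat;
  E.A.assign(ncat, std::vector<double>(stride));
  E.F.assign(ncat, std::vector<double>(stride));
  E.sA.assign(ncat, std::vector<double>(npat, 0.0));
  E.sF.assign(ncat, std::vector<double>(npat, 0.0));
  const int p = T.par[e], c = T.chd[e];
  // path root -> p
  std::vector<int> path;
  for (int x = p; x != 0; x = T.parentOf[x]) path.push_back(x);
  std::reverse(path.begin(), path.end()); // root ... p
  std::vector<double> part((size_t)(T.nNode + 1) * stride), scal(npat);
  std::vector<double> nodeScal((size_t)(T.nNode + 1) * npat);
  double P[16];
  for (int cat = 0; cat < ncat; ++cat) {
    // down partials with per-node scaler bookkeeping
    std::fill(part.begin(), part.end(), 1.0);
    std::fill(nodeScal.begin(), nodeScal.end(), 0.0);
    for (int n = 1; n <= T.nTip; ++n)
      std::copy(tip + (size_t)(n - 1) * stride, tip + (size_t)n * stride,
                part.begin() + (size_t)n * stride);
    for (int ee = 0; ee < T.nEdge; ++ee) {
      const int pp = T.par[ee], cc = T.chd[ee];
      double t = elen[ee]; if (t < MINBL) t = MINBL;
      pmat(M, t * M.rates[cat], P);
      const double* pcv = &part[(size_t)cc * stride];
      double* ppv = &part[(size_t)pp * stride];
      double* sc = &nodeScal[(size_t)pp * npat];
      const double* scc = &nodeScal[(size_t)cc * npat];
      for (int s = 0; s < npat; ++s) {
        const double* v = pcv + 4 * s;
        double* w = ppv + 4 * s;
        for (int i = 0; i < 4; ++i) {
          double x = P[i * 4 + 0] * v[0] + P[i * 4 + 1] * v[1] +
                     P[i * 4 + 2] * v[2] + P[i * 4 + 3] * v[3];
          w[i] *= x;
        }
        sc[s] += scc[s];
      }
    }
    // rescale pass is skipped here (node-exact scalers kept additive);
    // desk-scale trees stay within double range without it.
    // F = down partial of c
    std::copy(part.begin() + (size_t)c * stride,
              part.begin() + (size_t)(c + 1) * stride, E.F[cat].begin());
    std::copy(nodeScal.begin() + (size_t)c * npat,
              nodeScal.begin() + (size_t)(c + 1) * npat, E.sF[cat].begin());
    // A: walk root -> p
    std::vector<double> Acur(stride), Anext(stride), sAcur(npat, 0.0);
    for (int s = 0; s < npat; ++s)
      for (int i = 0; i < 4; ++i) Acur[4 * s + i] = M.pi[i];
    for (size_t step = 0; step < path.size(); ++step) {
      int x = path[step];
      int y = (step + 1 < path.size()) ? path[step + 1] : -1;
      // multiply in siblings at x (all child edges except the one toward y /
      // except edge e when x == p)
      for (int ce : T.kids[x]) {
        int cc = T.chd[ce];
        if (y >= 0 && cc == y) continue;
        if (x == p && ce == e) continue;
        double t = elen[ce]; if (t < MINBL) t = MINBL;
        pmat(M, t * M.rates[cat], P);
        const double* vv = &part[(size_t)cc * stride];
        const double* scc = &nodeScal[(size_t)cc * npat];
        for (int s = 0; s < npat; ++s) {
          const double* v = vv + 4 * s;
          double* w = &Acur[4 * s];
          for (int i = 0; i < 4; ++i) {
            double xm = P[i * 4 + 0] * v[0] + P[i * 4 + 1] * v[1] +
                        P[i * 4 + 2] * v[2] + P[i * 4 + 3] * v[3];
            w[i] *= xm;
          }
          sAcur[s] += scc[s];
        }
      }
      if (y < 0) break;
      // move through edge (x, y): A_y[j] = sum_i Acur[i] P_ij
      int ey = T.edgeToParent[y];
      double t = elen[ey]; if (t < MINBL) t = MINBL;
      pmat(M, t * M.rates[cat], P);
      for (int s = 0; s < npat; ++s) {
        const double* w = &Acur[4 * s];
        double* u = &Anext[4 * s];
        for (int j = 0; j < 4; ++j)
          u[j] = w[0] * P[0 * 4 + j] + w[1] * P[1 * 4 + j] +
                 w[2] * P[2 * 4 + j] + w[3] * P[3 * 4 + j];
      }
      std::swap(Acur, Anext);
    }
    // handle p == root (path length 1): loop above ran step 0 with y = -1
    E.A[cat] = Acur;
    E.sA[cat] = sAcur;
  }
  E.noscal = true;
  for (int cat = 0; cat < ncat && E.noscal; ++cat)
    for (int s = 0; s < npat; ++s)
      if (E.sA[cat][s] != 0.0 || E.sF[cat][s] != 0.0) { E.noscal = false; break; }
  return E;
}

static double edgeLogLik(const EdgeEnv& E, const Model& M, double t, int npat,
                         const NumericVector& invprod, const NumericVector& wts) {
  if (t < MINBL) t = MINBL;
  const int ncat = E.ncat;
  double total = 0.0;
  std::vector<double> Pc(16 * ncat);
  for (int cat = 0; cat < ncat; ++cat) pmat(M, t * M.rates[cat], &Pc[16 * cat]);
  if (E.noscal) {
    // fast path: mix raw per-category likelihoods, one log per pattern
    for (int s = 0; s < npat; ++s) {
      double mix = 0.0;
      for (int cat = 0; cat < ncat; ++cat) {
        const double* P = &Pc[16 * cat];
        const double* a = &E.A[cat][4 * s];
        const double* f = &E.F[cat][4 * s];
        double L = 0.0;
        for (int i = 0; i < 4; ++i) {
          double x = P[i * 4 + 0] * f[0] + P[i * 4 + 1] * f[1] +
                     P[i * 4 + 2] * f[2] + P[i * 4 + 3] * f[3];
          L += a[i] * x;
        }
        mix += L;
      }
      double lik = (1.0 - M.pinv) * mix / ncat + M.pinv * invprod[s];
      total += wts[s] * (lik > 0 ? std::log(lik) : -1e300);
    }
    return total;
  }
  std::vector<double> catll(ncat);
  const double lw = -std::log((double)ncat);
  for (int s = 0; s < npat; ++s) {
    for (int cat = 0; cat < ncat; ++cat) {
      const double* P = &Pc[16 * cat];
      const double* a = &E.A[cat][4 * s];
      const double* f = &E.F[cat][4 * s];
      double L = 0.0;
      for (int i = 0; i < 4; ++i) {
        double x = P[i * 4 + 0] * f[0] + P[i * 4 + 1] * f[1] +
                   P[i * 4 + 2] * f[2] + P[i * 4 + 3] * f[3];
        L += a[i] * x;
      }
      catll[cat] = (L > 0 ? std::log(L) : -1e300) + E.sA[cat][s] + E.sF[cat][s];
    }
    double m = -1e300;
    for (int c = 0; c < ncat; ++c) m = std::max(m, catll[c] + lw);
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += std::exp(catll[c] + lw - m);
    double lvar = m + std::log(acc);
    double ll;
    if (M.pinv > 0.0) {
      double a = std::log1p(-M.pinv) + lvar;
      if (invprod[s] > 0.0) {
        double b = std::log(M.pinv) + std::log(invprod[s]);
        double mm = std::max(a, b);
        ll = mm + std::log(std::exp(a - mm) + std::exp(b - mm));
      } else ll = a;
    } else ll = lvar;
    total += wts[s] * ll;
  }
  return total;
}

// golden-section maximization of f(log t) on [log lo, log hi]
template <typename F>
static double goldenMax(F f, double lo, double hi, double tol, int maxit) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(std::exp(c)), fd = f(std::exp(d));
  for (int it = 0; it < maxit && (b - a) > tol; ++it) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = f(std::exp(c)); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = f(std::exp(d)); }
  }
  return std::exp(0.5 * (a + b));
}

// [[Rcpp::export]]
List optim_edges_cpp(IntegerMatrix edge, int nTip, int nNode, int root,
                     NumericVector elen, NumericVector tippart, int npat,
                     NumericMatrix U, NumericMatrix Uinv,
                     NumericVector lam, NumericVector pi,
                     NumericVector rates, double pinv,
                     NumericVector invprod, NumericVector wts,
                     int maxSweeps, double tol) {
  Tree T = makeTree(edge, nTip, nNode, root);
  Model M = makeModel(U, Uinv, lam, pi, rates, pinv);
  const double* tip = REAL(tippart);
  NumericVector el = clone(elen);
  for (int i = 0; i < el.size(); ++i) if (el[i] < MINBL) el[i] = MINBL;
  double cur = totalLogLik(T, M, el, tip, npat, invprod, wts);
  const double init = cur;
  bool conv = false;
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    for (int e = 0; e < T.nEdge; ++e) {
      EdgeEnv E = edgeEnv(T, M, el, tip, npat, e);
      auto f = [&](double t) { return edgeLogLik(E, M, t, npat, invprod, wts); };
      double t0 = el[e];
      double t1 = goldenMax(f, 1e-9, 10.0, 1e-4, 60);
      if (f(t1) > f(t0)) el[e] = t1;
    }
    double now = totalLogLik(T, M, el, tip, npat, invprod, wts);
    if (now - cur < tol * (std::fabs(cur) + 1e-12)) { cur = std::max(now, cur); conv = true; break; }
    cur = now;
  }
  if (cur < init) { el = clone(elen); cur = init; } // never worse than input
  return List::create(_["elen"] = el, _["loglik"] = cur, _["converged"] = conv);
}
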