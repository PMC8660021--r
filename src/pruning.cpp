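// Core pruning passes for the two-state GTR model with free-rate
// categories. Layout: conditional-likelihood matrices are genes x nodes
// (column per node, contiguous), edges arrive in postorder so children
// are always processed before their parents.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline void edge_P(double pi0, double pi1, double len, double r,
                          double &P00, double &P01, double &P10, double &P11) {
  const double mu = 1.0 / (2.0 * pi0 * pi1);
  const double e = std::exp(-mu * len * r);
  P00 = pi0 + pi1 * e;
  P01 = pi1 * (1.0 - e);
  P10 = pi0 * (1.0 - e);
  P11 = pi1 + pi0 * e;
}

// Inside (Felsenstein) pass for one rate multiplier.
// tip0/tip1: genes x ntip partial indicators.
// [[Rcpp::export(name = ".cpp_down_pass")]]
List cpp_down_pass(IntegerMatrix edge, NumericVector lens, int ntip, int nnode,
                   NumericMatrix tip0, NumericMatrix tip1,
                   double pi0, double pi1, double r) {
  const int G = tip0.nrow(), nedge = edge.nrow();
  NumericMatrix L0(G, nnode), L1(G, nnode), lsc(G, nnode);
  NumericMatrix E0(G, nedge), E1(G, nedge);
  std::fill(L0.begin(), L0.end(), 1.0);
  std::fill(L1.begin(), L1.end(), 1.0);
  for (int i = 0; i < ntip; ++i) {
    std::copy(tip0.column(i).begin(), tip0.column(i).end(), L0.column(i).begin());
    std::copy(tip1.column(i).begin(), tip1.column(i).end(), L1.column(i).begin());
  }
  const double neg_inf = -std::numeric_limits<double>::infinity();
  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double P00, P01, P10, P11;
    edge_P(pi0, pi1, lens[e], r, P00, P01, P10, P11);
    double *l0p = &L0(0, p), *l1p = &L1(0, p), *sp = &lsc(0, p);
    const double *l0c = &L0(0, c), *l1c = &L1(0, c), *sc = &lsc(0, c);
    double *e0 = &E0(0, e), *e1 = &E1(0, e);
    for (int g = 0; g < G; ++g) {
      const double a = P00 * l0c[g] + P01 * l1c[g];
      const double b = P10 * l0c[g] + P11 * l1c[g];
      e0[g] = a; e1[g] = b;
      l0p[g] *= a; l1p[g] *= b;
      sp[g] += sc[g];
      const double m = l0p[g] > l1p[g] ? l0p[g] : l1p[g];
      if (m > 0.0 && m < 1e-120) {
        l0p[g] /= m; l1p[g] /= m; sp[g] += std::log(m);
      } else if (m == 0.0) {
        sp[g] = neg_inf;
      }
    }
  }
  return List::create(_["L0"] = L0, _["L1"] = L1, _["lsc"] = lsc,
                      _["E0"] = E0, _["E1"] = E1);
}

// Outside pass for one rate multiplier, given the matching inside pass.
// [[Rcpp::export(name = ".cpp_up_pass")]]
List cpp_up_pass(IntegerMatrix edge, NumericVector lens, int ntip, int nnode,
                 double pi0, double pi1, double r,
                 NumericMatrix lsc, NumericMatrix E0, NumericMatrix E1) {
  const int nedge = edge.nrow(), G = E0.nrow();
  const int root = ntip;  // 0-based: ape root index is ntip + 1
  NumericMatrix U0(G, nnode), U1(G, nnode), usc(G, nnode);
  std::fill(U0.column(root).begin(), U0.column(root).end(), pi0);
  std::fill(U1.column(root).begin(), U1.column(root).end(), pi1);
  std::vector< std::vector<int> > edges_of_parent(nnode);
  for (int e = 0; e < nedge; ++e) edges_of_parent[edge(e, 0) - 1].push_back(e);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  std::vector<double> A0(G), A1(G), asc(G);
  for (int e = nedge - 1; e >= 0; --e) {  // preorder
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double *u0p = &U0(0, p), *u1p = &U1(0, p), *up_sc = &usc(0, p);
    for (int g = 0; g < G; ++g) { A0[g] = u0p[g]; A1[g] = u1p[g]; asc[g] = up_sc[g]; }
    for (size_t si = 0; si < edges_of_parent[p].size(); ++si) {
      const int e2 = edges_of_parent[p][si];
      if (e2 == e) continue;
      const int c2 = edge(e2, 1) - 1;
      const double *f0 = &E0(0, e2), *f1 = &E1(0, e2), *s2 = &lsc(0, c2);
      for (int g = 0; g < G; ++g) {
        A0[g] *= f0[g]; A1[g] *= f1[g]; asc[g] += s2[g];
      }
    }
    double P00, P01, P10, P11;
    edge_P(pi0, pi1, lens[e], r, P00, P01, P10, P11);
    double *u0c = &U0(0, c), *u1c = &U1(0, c), *uc_sc = &usc(0, c);
    for (int g = 0; g < G; ++g) {
      u0c[g] = A0[g] * P00 + A1[g] * P10;
      u1c[g] = A0[g] * P01 + A1[g] * P11;
      uc_sc[g] = asc[g];
      const double m = u0c[g] > u1c[g] ? u0c[g] : u1c[g];
      if (m > 0.0 && m < 1e-120) {
        u0c[g] /= m; u1c[g] /= m; uc_sc[g] += std::log(m);
      } else if (m == 0.0) {
        uc_sc[g] = neg_inf;
      }
    }
  }
  return List::create(_["U0"] = U0, _["U1"] = U1, _["usc"] = usc);
}

// ---- raw-buffer passes shared by the exported functions and the sweep ------

struct Workspace {
  int G, nnode, nedge, ntip;
  std::vector<double> L0, L1, lsc, E0, E1, U0, U1, usc;
  Workspace(int G_, int nnode_, int nedge_, int ntip_)
      : G(G_), nnode(nnode_), nedge(nedge_), ntip(ntip_),
        L0(G_ * nnode_), L1(G_ * nnode_), lsc(G_ * nnode_),
        E0(G_ * nedge_), E1(G_ * nedge_),
        U0(G_ * nnode_), U1(G_ * nnode_), usc(G_ * nnode_) {}
};

static void down_pass_raw(const IntegerMatrix &edge, const double *lens,
                          const NumericMatrix &tip0, const NumericMatrix &tip1,
                          double pi0, double pi1, double r, Workspace &w) {
  const int G = w.G, nedge = w.nedge;
  const double neg_inf = -std::numeric_limits<double>::infinity();
  std::fill(w.L0.begin(), w.L0.end(), 1.0);
  std::fill(w.L1.begin(), w.L1.end(), 1.0);
  std::fill(w.lsc.begin(), w.lsc.end(), 0.0);
  for (int i = 0; i < w.ntip; ++i)
    for (int g = 0; g < G; ++g) {
      w.L0[i * G + g] = tip0(g, i);
      w.L1[i * G + g] = tip1(g, i);
    }
  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double P00, P01, P10, P11;
    edge_P(pi0, pi1, lens[e], r, P00, P01, P10, P11);
    double *l0p = &w.L0[p * G], *l1p = &w.L1[p * G], *sp = &w.lsc[p * G];
    const double *l0c = &w.L0[c * G], *l1c = &w.L1[c * G], *sc = &w.lsc[c * G];
    double *e0 = &w.E0[e * G], *e1 = &w.E1[e * G];
    for (int g = 0; g < G; ++g) {
      const double a = P00 * l0c[g] + P01 * l1c[g];
      const double b = P10 * l0c[g] + P11 * l1c[g];
      e0[g] = a; e1[g] = b;
      l0p[g] *= a; l1p[g] *= b; sp[g] += sc[g];
      const double m = l0p[g] > l1p[g] ? l0p[g] : l1p[g];
      if (m > 0.0 && m < 1e-120) {
        l0p[g] /= m; l1p[g] /= m; sp[g] += std::log(m);
      } else if (m == 0.0) {
        sp[g] = neg_inf;
      }
    }
  }
}

static void up_pass_raw(const IntegerMatrix &edge, const double *lens,
                        double pi0, double pi1, double r,
                        const std::vector< std::vector<int> > &edges_of_parent,
                        Workspace &w) {
  const int G = w.G, nedge = w.nedge, root = w.ntip;
  const double neg_inf = -std::numeric_limits<double>::infinity();
  std::fill(w.U0.begin(), w.U0.end(), 0.0);
  std::fill(w.U1.begin(), w.U1.end(), 0.0);
  std::fill(w.usc.begin(), w.usc.end(), 0.0);
  std::fill(w.U0.begin() + root * G, w.U0.begin() + (root + 1) * G, pi0);
  std::fill(w.U1.begin() + root * G, w.U1.begin() + (root + 1) * G, pi1);
  std::vector<double> A0(G), A1(G), asc(G);
  for (int e = nedge - 1; e >= 0; --e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int g = 0; g < G; ++g) {
      A0[g] = w.U0[p * G + g]; A1[g] = w.U1[p * G + g]; asc[g] = w.usc[p * G + g];
    }
    for (size_t si = 0; si < edges_of_parent[p].size(); ++si) {
      const int e2 = edges_of_parent[p][si];
      if (e2 == e) continue;
      const int c2 = edge(e2, 1) - 1;
      const double *f0 = &w.E0[e2 * G], *f1 = &w.E1[e2 * G], *s2 = &w.lsc[c2 * G];
      for (int g = 0; g < G; ++g) {
        A0[g] *= f0[g]; A1[g] *= f1[g]; asc[g] += s2[g];
      }
    }
    double P00, P01, P10, P11;
    edge_P(pi0, pi1, lens[e], r, P00, P01, P10, P11);
    double *u0c = &w.U0[c * G], *u1c = &w.U1[c * G], *uc_sc = &w.usc[c * G];
    for (int g = 0; g < G; ++g) {
      u0c[g] = A0[g] * P00 + A1[g] * P10;
      u1c[g] = A0[g] * P01 + A1[g] * P11;
      uc_sc[g] = asc[g];
      const double m = u0c[g] > u1c[g] ? u0c[g] : u1c[g];
      if (m > 0.0 && m < 1e-120) {
        u0c[g] /= m; u1c[g] /= m; uc_sc[g] += std::log(m);
      } else if (m == 0.0) {
        uc_sc[g] = neg_inf;
      }
    }
  }
}

// Profile of the weighted total log-likelihood in one branch length, with
// all other branches fixed; cached outside (A) and inside (D) terms.
struct EdgeProfile {
  int G, K;
  double pi0, pi1;
  const double *weights, *rates;
  const double *wts;
  // per category, length G each
  std::vector< std::vector<double> > A0, A1, D0, D1, sc;
  double operator()(double t) const {
    const double mu = 1.0 / (2.0 * pi0 * pi1);
    std::vector<double> P00(K), P01(K), P10(K), P11(K), logw(K), lk(K);
    for (int k = 0; k < K; ++k) {
      const double e = std::exp(-mu * t * rates[k]);
      P00[k] = pi0 + pi1 * e; P01[k] = pi1 * (1.0 - e);
      P10[k] = pi0 * (1.0 - e); P11[k] = pi1 + pi0 * e;
      logw[k] = std::log(weights[k]);
    }
    double total = 0.0;
    for (int g = 0; g < G; ++g) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        const double lik = A0[k][g] * (P00[k] * D0[k][g] + P01[k] * D1[k][g]) +
                           A1[k][g] * (P10[k] * D0[k][g] + P11[k] * D1[k][g]);
        lk[k] = (lik > 0.0 ? std::log(lik) : -std::numeric_limits<double>::infinity()) +
                sc[k][g] + logw[k];
        if (lk[k] > mx) mx = lk[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(lk[k] - mx);
      total += wts[g] * (mx + std::log(s));
    }
    return total;
  }
};

// Brent maximization on [a, b] (golden section with parabolic steps).
static double brent_max(const EdgeProfile &f, double a, double b, double tol,
                        double &fmax) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      const double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      const double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm ? a - x : b - x);
      d = gold * e;
    }
    const double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
    const double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) {
        v = w; w = u; fv = fw; fw = fu;
      } else if (fu >= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  fmax = fx;
  return x;
}

// One (or more) exact coordinate-ascent sweeps over all branch lengths.
// Returns updated lengths and the final total log-likelihood.
// [[Rcpp::export(name = ".cpp_branch_sweep")]]
List cpp_branch_sweep(IntegerMatrix edge, NumericVector lens0, int ntip, int nnode,
                      NumericMatrix tip0, NumericMatrix tip1,
                      double pi0, double pi1,
                      NumericVector weights, NumericVector rates,
                      NumericVector wts, double lower, double upper,
                      int sweeps, double tol, double stale_tol = 0.0) {
  const int G = tip0.nrow(), K = rates.size(), nedge = edge.nrow();
  std::vector<double> lens(lens0.begin(), lens0.end());
  std::vector< std::vector<int> > edges_of_parent(nnode);
  for (int e = 0; e < nedge; ++e) edges_of_parent[edge(e, 0) - 1].push_back(e);
  std::vector<Workspace> ws;
  for (int k = 0; k < K; ++k) ws.emplace_back(G, nnode, nedge, ntip);
  EdgeProfile prof;
  prof.G = G; prof.K = K; prof.pi0 = pi0; prof.pi1 = pi1;
  prof.weights = weights.begin(); prof.rates = rates.begin();
  prof.wts = wts.begin();
  prof.A0.assign(K, std::vector<double>(G));
  prof.A1.assign(K, std::vector<double>(G));
  prof.D0.assign(K, std::vector<double>(G));
  prof.D1.assign(K, std::vector<double>(G));
  prof.sc.assign(K, std::vector<double>(G));
  double ll = -std::numeric_limits<double>::infinity();
  // partials are recomputed lazily: exact when stale_tol = 0, otherwise
  // reused until accumulated branch-length movement exceeds stale_tol
  double stale = std::numeric_limits<double>::infinity();
  for (int sweep = 0; sweep < sweeps; ++sweep) {
    double ll_start = ll;
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      if (stale > stale_tol) {
        for (int k = 0; k < K; ++k) {
          down_pass_raw(edge, lens.data(), tip0, tip1, pi0, pi1, rates[k], ws[k]);
          up_pass_raw(edge, lens.data(), pi0, pi1, rates[k], edges_of_parent, ws[k]);
        }
        stale = 0.0;
      }
      for (int k = 0; k < K; ++k) {
        Workspace &w = ws[k];
        for (int g = 0; g < G; ++g) {
          double a0 = w.U0[p * G + g], a1 = w.U1[p * G + g];
          double asc = w.usc[p * G + g];
          for (size_t si = 0; si < edges_of_parent[p].size(); ++si) {
            const int e2 = edges_of_parent[p][si];
            if (e2 == e) continue;
            const int c2 = edge(e2, 1) - 1;
            a0 *= w.E0[e2 * G + g]; a1 *= w.E1[e2 * G + g];
            asc += w.lsc[c2 * G + g];
          }
          prof.A0[k][g] = a0; prof.A1[k][g] = a1;
          prof.D0[k][g] = w.L0[c * G + g]; prof.D1[k][g] = w.L1[c * G + g];
          prof.sc[k][g] = asc + w.lsc[c * G + g];
        }
      }
      const double f_cur = prof(lens[e]);
      double f_new;
      const double t_new = brent_max(prof, lower, upper, 1e-8, f_new);
      if (f_new > f_cur) {
        stale += std::fabs(t_new - lens[e]);
        lens[e] = t_new;
        ll = f_new;
      } else {
        ll = f_cur;
      }
    }
    if (sweep > 0 && ll - ll_start < tol) break;
  }
  return List::create(_["lens"] = NumericVector(lens.begin(), lens.end()),
                      _["loglik"] = ll);
}

// Per-gene log-likelihoods, one column per rate category (no weighting).
// [[Rcpp::export(name = ".cpp_category_logliks")]]
NumericMatrix cpp_category_logliks(IntegerMatrix edge, NumericVector lens,
                                   int ntip, int nnode,
                                   NumericMatrix tip0, NumericMatrix tip1,
                                   double pi0, double pi1, NumericVector rates) {
  const int G = tip0.nrow(), K = rates.size(), nedge = edge.nrow();
  const int root = ntip;
  NumericMatrix out(G, K);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  std::vector<double> L0(G * nnode), L1(G * nnode), gsc(G);
  for (int k = 0; k < K; ++k) {
    std::fill(L0.begin(), L0.end(), 1.0);
    std::fill(L1.begin(), L1.end(), 1.0);
    std::fill(gsc.begin(), gsc.end(), 0.0);
    for (int i = 0; i < ntip; ++i) {
      for (int g = 0; g < G; ++g) {
        L0[i * G + g] = tip0(g, i);
        L1[i * G + g] = tip1(g, i);
      }
    }
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      double P00, P01, P10, P11;
      edge_P(pi0, pi1, lens[e], rates[k], P00, P01, P10, P11);
      double *l0p = &L0[p * G], *l1p = &L1[p * G];
      const double *l0c = &L0[c * G], *l1c = &L1[c * G];
      for (int g = 0; g < G; ++g) {
        const double a = P00 * l0c[g] + P01 * l1c[g];
        const double b = P10 * l0c[g] + P11 * l1c[g];
        l0p[g] *= a; l1p[g] *= b;
        const double m = l0p[g] > l1p[g] ? l0p[g] : l1p[g];
        // every node's rescale factor reaches the root product exactly
        // once, so one per-gene accumulator suffices for the total
        if (m > 0.0 && m < 1e-120) {
          l0p[g] /= m; l1p[g] /= m; gsc[g] += std::log(m);
        } else if (m == 0.0) {
          gsc[g] = neg_inf;
        }
      }
    }
    for (int g = 0; g < G; ++g) {
      const double rl = pi0 * L0[root * G + g] + pi1 * L1[root * G + g];
      out(g, k) = (rl > 0.0 ? std::log(rl) : neg_inf) + gsc[g];
    }
  }
  return out;
}
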