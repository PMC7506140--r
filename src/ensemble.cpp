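// Random-circuit-perturbation style solver: generic N-node shifted-Hill
// network dynamics, relaxation from many initial conditions to stable
// steady states.
//
// dx_i/dt = g_i * prod_{edges j->i} Hs(x_j, A0, n, lambda) - k_i * x_i
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double shill(double x, double x0, double n, double lam) {
  double r = std::pow(x / x0, n);
  return (1.0 + lam * r) / (1.0 + r);
}

struct Net {
  int nn, ne;
  std::vector<int> src, tgt;
  std::vector<double> lam, hn, a0, g, k;
};

static void net_rhs(const Net& w, const double* x, double* dx) {
  for (int i = 0; i < w.nn; ++i) dx[i] = w.g[i];
  for (int e = 0; e < w.ne; ++e)
    dx[w.tgt[e]] *= shill(x[w.src[e]], w.a0[e], w.hn[e], w.lam[e]);
  for (int i = 0; i < w.nn; ++i) dx[i] -= w.k[i] * x[i];
}

// adaptive forward-Euler relaxation to steady state; returns true if the
// relative sup-norm of the rhs dropped below tol within max_steps
static bool relax(const Net& w, double* x, double tol, long max_steps) {
  int n = w.nn;
  std::vector<double> dx(n), xn(n);
  double dt = 0.1;
  for (long s = 0; s < max_steps; ++s) {
    net_rhs(w, x, dx.data());
    double rel = 0.0;
    for (int i = 0; i < n; ++i)
      rel = std::max(rel, std::fabs(dx[i]) / std::max(std::fabs(x[i]), 1.0));
    if (rel < tol) return true;
    // tentative step; shrink if it overshoots (sign of instability)
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      xn[i] = x[i] + dt * dx[i];
      if (!std::isfinite(xn[i]) || xn[i] < -0.1 * std::fabs(x[i]) - 1.0) ok = false;
    }
    if (!ok) { dt *= 0.5; if (dt < 1e-6) return false; continue; }
    double chg = 0.0;
    for (int i = 0; i < n; ++i)
      chg = std::max(chg, std::fabs(xn[i] - x[i]) / std::max(std::fabs(x[i]), 1.0));
    if (chg > 0.2) { dt *= 0.5; if (dt < 1e-6) return false; continue; }
    for (int i = 0; i < n; ++i) x[i] = std::max(xn[i], 0.0);
    if (chg < 0.02 && dt < 2.0) dt *= 1.3;
  }
  return false;
}

static double lead_eig_net(const Net& w, const double* x) {
  int n = w.nn;
  arma::mat J(n, n);
  std::vector<double> f0(n), f1(n), xp(n);
  net_rhs(w, x, f0.data());
  for (int j = 0; j < n; ++j) {
    std::copy(x, x + n, xp.begin());
    double h = std::max(1e-6 * std::fabs(x[j]), 1e-6);
    xp[j] += h;
    net_rhs(w, xp.data(), f1.data());
    for (int i = 0; i < n; ++i) J(i, j) = (f1[i] - f0[i]) / h;
  }
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, J)) return NA_REAL;
  return arma::real(ev).max();
}

// [[Rcpp::export]]
NumericVector cpp_net_rhs(NumericVector state, IntegerVector src, IntegerVector tgt,
                          NumericVector lam, NumericVector hilln, NumericVector a0,
                          NumericVector g, NumericVector k) {
  Net w;
  w.nn = state.size(); w.ne = src.size();
  w.src.assign(src.begin(), src.end()); w.tgt.assign(tgt.begin(), tgt.end());
  w.lam.assign(lam.begin(), lam.end()); w.hn.assign(hilln.begin(), hilln.end());
  w.a0.assign(a0.begin(), a0.end());
  w.g.assign(g.begin(), g.end()); w.k.assign(k.begin(), k.end());
  NumericVector out(w.nn);
  net_rhs(w, state.begin(), out.begin());
  return out;
}

// Solve one sampled model from many initial conditions.
// edges: src/tgt are 0-based node indices.  inits: one start per row.
// Returns list(states = matrix of deduplicated stable states (rows),
//              arrivals = integer vector mapping each init to a state row
//                         (0 = unresolved / discarded),
//              n_unresolved)
// [[Rcpp::export]]
List cpp_solve_model(IntegerVector src, IntegerVector tgt,
                     NumericVector lam, NumericVector hilln, NumericVector a0,
                     NumericVector g, NumericVector k, NumericMatrix inits,
                     double tol = 1e-6, double dedup_log_tol = 0.05,
                     double max_steps = 200000) {
  Net w;
  w.nn = g.size(); w.ne = src.size();
  w.src.assign(src.begin(), src.end()); w.tgt.assign(tgt.begin(), tgt.end());
  w.lam.assign(lam.begin(), lam.end()); w.hn.assign(hilln.begin(), hilln.end());
  w.a0.assign(a0.begin(), a0.end());
  w.g.assign(g.begin(), g.end()); w.k.assign(k.begin(), k.end());
  int n = w.nn, ni = inits.nrow();
  std::vector<std::vector<double>> states;
  IntegerVector arrivals(ni);
  int unresolved = 0;
  std::vector<double> x(n);
  for (int s = 0; s < ni; ++s) {
    for (int i = 0; i < n; ++i) x[i] = inits(s, i);
    if (!relax(w, x.data(), tol, (long)max_steps)) { ++unresolved; arrivals[s] = 0; continue; }
    // match against known states in log space
    int hit = 0;
    for (size_t q = 0; q < states.size(); ++q) {
      bool same = true;
      for (int i = 0; i < n; ++i) {
        double a = std::log(std::max(x[i], 1e-3)), b = std::log(std::max(states[q][i], 1e-3));
        if (std::fabs(a - b) > dedup_log_tol) { same = false; break; }
      }
      if (same) { hit = (int)q + 1; break; }
    }
    if (!hit) {
      if (lead_eig_net(w, x.data()) < -1e-8) {
        states.push_back(std::vector<double>(x.begin(), x.end()));
        hit = (int)states.size();
      } else { ++unresolved; arrivals[s] = 0; continue; }
    }
    arrivals[s] = hit;
  }
  NumericMatrix sm(states.size(), n);
  for (size_t q = 0; q < states.size(); ++q)
    for (int i = 0; i < n; ++i) sm(q, i) = states[q][i];
  return List::create(_["states"] = sm, _["arrivals"] = arrivals,
                      _["n_unresolved"] = unresolved);
}
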