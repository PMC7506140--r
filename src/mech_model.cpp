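// Mechanistic miR-200/ZEB/SNAIL/E-cad/NFATc circuit: right-hand side,
// Newton steady-state search and stability classification.
//
// State ordering everywhere: (mu, mz, Z, E, N) = miR-200, ZEB mRNA,
// ZEB protein, E-cadherin, NFATc.  SNAIL (S) is a clamped external input.
// Units: molecules and hours.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NSPEC = 5;

// shifted Hill: (1 + lam*(x/x0)^n) / (1 + (x/x0)^n)
static inline double shill(double x, double x0, double n, double lam) {
  if (lam == 1.0) return 1.0;
  double r = std::pow(x / x0, n);
  return (1.0 + lam * r) / (1.0 + r);
}

// Parameter block passed from R as a named list, flattened here once.
struct MechPar {
  double gu, ku, gm, km, gz, kz, gE, kE, gN, kN;
  // Hill blocks: {A0, n, lambda}
  double Z0u, nZu, lZu;  // ZEB protein -| miR-200
  double S0u, nSu, lSu;  // SNAIL -| miR-200
  double N0u, nNu, lNu;  // NFATc -> miR-200
  double Z0m, nZm, lZm;  // ZEB -> ZEB mRNA (self-activation)
  double S0m, nSm, lSm;  // SNAIL -> ZEB mRNA
  double N0m, nNm, lNm;  // NFATc -> ZEB mRNA
  double E0m, nEm, lEm;  // E-cad -| ZEB mRNA (indirect)
  double Z0E, nZE, lZE;  // ZEB -| E-cad
  double N0E, nNE, lNE;  // NFATc -> E-cad
  // microRNA binding-site coupling (miR-200 -> ZEB mRNA)
  double mu0;
  int nsite;
  std::vector<double> li, gmi, gui;
};

static MechPar unpack(const List& p) {
  MechPar q;
  q.gu = p["gu"]; q.ku = p["ku"]; q.gm = p["gm"]; q.km = p["km"];
  q.gz = p["gz"]; q.kz = p["kz"]; q.gE = p["gE"]; q.kE = p["kE"];
  q.gN = p["gN"]; q.kN = p["kN"];
  q.Z0u = p["Z0u"]; q.nZu = p["nZu"]; q.lZu = p["lZu"];
  q.S0u = p["S0u"]; q.nSu = p["nSu"]; q.lSu = p["lSu"];
  q.N0u = p["N0u"]; q.nNu = p["nNu"]; q.lNu = p["lNu"];
  q.Z0m = p["Z0m"]; q.nZm = p["nZm"]; q.lZm = p["lZm"];
  q.S0m = p["S0m"]; q.nSm = p["nSm"]; q.lSm = p["lSm"];
  q.N0m = p["N0m"]; q.nNm = p["nNm"]; q.lNm = p["lNm"];
  q.E0m = p["E0m"]; q.nEm = p["nEm"]; q.lEm = p["lEm"];
  q.Z0E = p["Z0E"]; q.nZE = p["nZE"]; q.lZE = p["lZE"];
  q.N0E = p["N0E"]; q.nNE = p["nNE"]; q.lNE = p["lNE"];
  q.mu0 = p["mu0"];
  NumericVector li = p["l_i"], gmi = p["gamma_m"], gui = p["gamma_mu"];
  q.nsite = li.size() - 1;
  q.li.assign(li.begin(), li.end());
  q.gmi.assign(gmi.begin(), gmi.end());
  q.gui.assign(gui.begin(), gui.end());
  return q;
}

// binomial occupancy sums L(mu), Ym(mu), Ymu(mu)
static void mir_sums(const MechPar& q, double mu, double& L, double& Ym, double& Ymu) {
  double r = mu / q.mu0, w = 1.0, denom = std::pow(1.0 + r, q.nsite);
  L = 0.0; Ym = 0.0; Ymu = 0.0;
  for (int i = 0; i <= q.nsite; ++i) {
    double Mi = w / denom;
    L += q.li[i] * Mi;
    Ym += q.gmi[i] * Mi;
    Ymu += i * q.gui[i] * Mi;
    // next binomial term: C(n,i+1) r^{i+1} = C(n,i) r^i * (n-i)/(i+1) * r
    w *= r * (q.nsite - i) / (i + 1.0);
  }
}

static void mech_rhs(const MechPar& q, const double* x, double S, double* dx) {
  double mu = x[0], mz = x[1], Z = x[2], E = x[3], N = x[4];
  double L, Ym, Ymu;
  mir_sums(q, mu, L, Ym, Ymu);
  double hu = shill(Z, q.Z0u, q.nZu, q.lZu) * shill(S, q.S0u, q.nSu, q.lSu) *
              shill(N, q.N0u, q.nNu, q.lNu);
  double hm = shill(Z, q.Z0m, q.nZm, q.lZm) * shill(S, q.S0m, q.nSm, q.lSm) *
              shill(N, q.N0m, q.nNm, q.lNm) * shill(E, q.E0m, q.nEm, q.lEm);
  double hE = shill(Z, q.Z0E, q.nZE, q.lZE) * shill(N, q.N0E, q.nNE, q.lNE);
  dx[0] = q.gu * hu - mz * Ymu - q.ku * mu;
  dx[1] = q.gm * hm - mz * Ym - q.km * mz;
  dx[2] = q.gz * mz * L - q.kz * Z;
  dx[3] = q.gE * hE - q.kE * E;
  dx[4] = q.gN - q.kN * N;
}

// [[Rcpp::export]]
NumericVector cpp_mech_rhs(NumericVector state, List params, double S) {
  MechPar q = unpack(params);
  NumericVector out(NSPEC);
  mech_rhs(q, state.begin(), S, out.begin());
  return out;
}

static void num_jac(const MechPar& q, const double* x, double S, arma::mat& J) {
  double f0[NSPEC], f1[NSPEC], xp[NSPEC];
  mech_rhs(q, x, S, f0);
  for (int j = 0; j < NSPEC; ++j) {
    std::copy(x, x + NSPEC, xp);
    double h = std::max(1e-6 * std::fabs(x[j]), 1e-6);
    xp[j] += h;
    mech_rhs(q, xp, S, f1);
    for (int i = 0; i < NSPEC; ++i) J(i, j) = (f1[i] - f0[i]) / h;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_mech_jacobian(NumericVector state, List params, double S) {
  MechPar q = unpack(params);
  arma::mat J(NSPEC, NSPEC);
  num_jac(q, state.begin(), S, J);
  return wrap(J);
}

// damped Newton from x0; returns true on convergence
static bool newton(const MechPar& q, double* x, double S,
                   double ftol, int maxit) {
  arma::mat J(NSPEC, NSPEC);
  arma::vec f(NSPEC), dx;
  for (int it = 0; it < maxit; ++it) {
    mech_rhs(q, x, S, f.memptr());
    double fn = arma::norm(f, "inf");
    if (fn < ftol) return true;
    num_jac(q, x, S, J);
    if (!arma::solve(dx, J, -f, arma::solve_opts::no_approx)) return false;
    // damped update, clipped to the non-negative orthant
    double step = 1.0;
    for (int tries = 0; tries < 30; ++tries) {
      bool ok = true;
      double xn[NSPEC];
      for (int i = 0; i < NSPEC; ++i) {
        xn[i] = x[i] + step * dx(i);
        if (xn[i] < 0) xn[i] = 0.0;
        if (!std::isfinite(xn[i])) ok = false;
      }
      if (ok) { std::copy(xn, xn + NSPEC, x); break; }
      step *= 0.5;
    }
  }
  mech_rhs(q, x, S, f.memptr());
  return arma::norm(f, "inf") < ftol;
}

static double lead_eig(const MechPar& q, const double* x, double S) {
  arma::mat J(NSPEC, NSPEC);
  num_jac(q, x, S, J);
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, J)) return NA_REAL;
  return arma::real(ev).max();
}

// log-scale dedup: roots identical if max |log ratio| (floored at 1 molecule)
// is below log(1 + reltol)
static bool same_root(const double* a, const double* b, double reltol) {
  for (int i = 0; i < NSPEC; ++i) {
    double la = std::log(std::max(a[i], 1.0)), lb = std::log(std::max(b[i], 1.0));
    if (std::fabs(la - lb) > reltol) return false;
  }
  return true;
}

// Multi-start steady-state search.  `starts` is a matrix with one initial
// point per row.  Returns matrix [mu mz Z E N eig] sorted by mz.
// [[Rcpp::export]]
NumericMatrix cpp_mech_steady_states(List params, double S, NumericMatrix starts,
                                     double ftol = 1e-8, double dedup_tol = 1e-2,
                                     int maxit = 200) {
  MechPar q = unpack(params);
  std::vector<std::array<double, NSPEC>> roots;
  double x[NSPEC];
  double ldt = std::log(1.0 + dedup_tol) * 5.0;  // generous merge radius in log space
  for (int s = 0; s < starts.nrow(); ++s) {
    for (int i = 0; i < NSPEC; ++i) x[i] = starts(s, i);
    if (!newton(q, x, S, ftol, maxit)) continue;
    bool dup = false;
    for (auto& r : roots) if (same_root(x, r.data(), ldt)) { dup = true; break; }
    if (!dup) {
      std::array<double, NSPEC> r;
      std::copy(x, x + NSPEC, r.begin());
      roots.push_back(r);
    }
  }
  // sort by ZEB mRNA level
  std::sort(roots.begin(), roots.end(),
            [](const std::array<double, NSPEC>& a, const std::array<double, NSPEC>& b) {
              return a[1] < b[1];
            });
  NumericMatrix out(roots.size(), NSPEC + 1);
  for (size_t i = 0; i < roots.size(); ++i) {
    for (int j = 0; j < NSPEC; ++j) out(i, j) = roots[i][j];
    out(i, NSPEC) = lead_eig(q, roots[i].data(), S);
  }
  colnames(out) = CharacterVector::create("mu", "mz", "Z", "E", "N", "eig");
  return out;
}

// Fixed-step RK4 integration to a horizon (used internally for basin probes
// and as a cheap relaxation device; user-facing trajectories go through
// deSolve on the R side).
// [[Rcpp::export]]
NumericVector cpp_mech_relax(NumericVector state, List params, double S,
                             double t_max, double dt = 0.05) {
  MechPar q = unpack(params);
  double x[NSPEC], k1[NSPEC], k2[NSPEC], k3[NSPEC], k4[NSPEC], tmp[NSPEC];
  std::copy(state.begin(), state.end(), x);
  long nstep = (long)std::ceil(t_max / dt);
  for (long s = 0; s < nstep; ++s) {
    mech_rhs(q, x, S, k1);
    for (int i = 0; i < NSPEC; ++i) tmp[i] = std::max(x[i] + 0.5 * dt * k1[i], 0.0);
    mech_rhs(q, tmp, S, k2);
    for (int i = 0; i < NSPEC; ++i) tmp[i] = std::max(x[i] + 0.5 * dt * k2[i], 0.0);
    mech_rhs(q, tmp, S, k3);
    for (int i = 0; i < NSPEC; ++i) tmp[i] = std::max(x[i] + dt * k3[i], 0.0);
    mech_rhs(q, tmp, S, k4);
    for (int i = 0; i < NSPEC; ++i)
      x[i] = std::max(x[i] + dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]), 0.0);
  }
  NumericVector out(x, x + NSPEC);
  out.names() = CharacterVector::create("mu", "mz", "Z", "E", "N");
  return out;
}
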