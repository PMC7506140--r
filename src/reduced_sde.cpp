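// Quasi-steady-state reduced (ZEB protein, miR-200) system: deterministic
// drift, basin-assignment grid, and Euler-Maruyama simulation with on-line
// itinerary coarse-graining and 2-D histogram accumulation.
//
// The reduced drift eliminates ZEB mRNA, E-cadherin and NFATc by setting
// their time derivatives to zero; closures are evaluated in closed form so
// fixed points coincide with the full model's.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct RedPar {
  double gu, ku, gm, km, gz, kz, gE, kE, gN, kN;
  double Z0u, nZu, lZu, S0u, nSu, lSu, N0u, nNu, lNu;
  double Z0m, nZm, lZm, S0m, nSm, lSm, N0m, nNm, lNm;
  double E0m, nEm, lEm, Z0E, nZE, lZE, N0E, nNE, lNE;
  double mu0;
  int nsite;
  std::vector<double> li, gmi, gui;
  double S;  // clamped SNAIL input
};

static inline double shill(double x, double x0, double n, double lam) {
  if (lam == 1.0) return 1.0;
  double r = std::pow(x / x0, n);
  return (1.0 + lam * r) / (1.0 + r);
}

static RedPar unpack_red(const List& p, double S) {
  RedPar q;
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
  q.S = S;
  return q;
}

static void mir_sums(const RedPar& q, double mu, double& L, double& Ym, double& Ymu) {
  double r = mu / q.mu0, w = 1.0, denom = std::pow(1.0 + r, q.nsite);
  L = 0.0; Ym = 0.0; Ymu = 0.0;
  for (int i = 0; i <= q.nsite; ++i) {
    double Mi = w / denom;
    L += q.li[i] * Mi;
    Ym += q.gmi[i] * Mi;
    Ymu += i * q.gui[i] * Mi;
    w *= r * (q.nsite - i) / (i + 1.0);
  }
}

// drift of the reduced (Z, mu) system; also returns the lifted closures
static void red_drift(const RedPar& q, double Z, double mu,
                      double& dZ, double& dmu,
                      double* mz_out = nullptr, double* E_out = nullptr) {
  double N = q.gN / q.kN;
  double E = q.gE * shill(Z, q.Z0E, q.nZE, q.lZE) * shill(N, q.N0E, q.nNE, q.lNE) / q.kE;
  double L, Ym, Ymu;
  mir_sums(q, mu, L, Ym, Ymu);
  double hm = shill(Z, q.Z0m, q.nZm, q.lZm) * shill(q.S, q.S0m, q.nSm, q.lSm) *
              shill(N, q.N0m, q.nNm, q.lNm) * shill(E, q.E0m, q.nEm, q.lEm);
  double mz = q.gm * hm / (Ym + q.km);
  double hu = shill(Z, q.Z0u, q.nZu, q.lZu) * shill(q.S, q.S0u, q.nSu, q.lSu) *
              shill(N, q.N0u, q.nNu, q.lNu);
  dmu = q.gu * hu - mz * Ymu - q.ku * mu;
  dZ = q.gz * mz * L - q.kz * Z;
  if (mz_out) *mz_out = mz;
  if (E_out) *E_out = E;
}

// [[Rcpp::export]]
NumericVector cpp_red_drift(double Z, double mu, List params, double S) {
  RedPar q = unpack_red(params, S);
  double dZ, dmu, mz, E;
  red_drift(q, Z, mu, dZ, dmu, &mz, &E);
  return NumericVector::create(_["dZ"] = dZ, _["dmu"] = dmu,
                               _["mz"] = mz, _["E"] = E);
}

// RK4 relaxation of the reduced drift for t_max hours.  Stops early once
// the drift is negligible relative to the state (fixed point reached).
static void red_relax(const RedPar& q, double& Z, double& mu, double t_max, double dt) {
  long n = (long)std::ceil(t_max / dt);
  for (long s = 0; s < n; ++s) {
    if (s % 200 == 0) {
      double dZ, dmu;
      red_drift(q, Z, mu, dZ, dmu);
      if (std::fabs(dZ) < 1e-7 * std::max(Z, 1.0) &&
          std::fabs(dmu) < 1e-7 * std::max(mu, 1.0)) return;
    }
    double k1z, k1u, k2z, k2u, k3z, k3u, k4z, k4u;
    red_drift(q, Z, mu, k1z, k1u);
    red_drift(q, std::max(Z + 0.5 * dt * k1z, 0.0), std::max(mu + 0.5 * dt * k1u, 0.0), k2z, k2u);
    red_drift(q, std::max(Z + 0.5 * dt * k2z, 0.0), std::max(mu + 0.5 * dt * k2u, 0.0), k3z, k3u);
    red_drift(q, std::max(Z + dt * k3z, 0.0), std::max(mu + dt * k3u, 0.0), k4z, k4u);
    Z = std::max(Z + dt / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z), 0.0);
    mu = std::max(mu + dt / 6.0 * (k1u + 2 * k2u + 2 * k3u + k4u), 0.0);
  }
}

// [[Rcpp::export]]
NumericVector cpp_red_relax(double Z, double mu, List params, double S,
                            double t_max, double dt = 0.05) {
  RedPar q = unpack_red(params, S);
  red_relax(q, Z, mu, t_max, dt);
  return NumericVector::create(_["Z"] = Z, _["mu"] = mu);
}

// Assign each point of a log-spaced grid to the basin of one of the supplied
// attractors by deterministic relaxation.  attractors: matrix [Z, mu] rows.
// Returns integer matrix (nZ x nMu) of 1-based attractor indices
// (0 = unresolved within horizon).
// [[Rcpp::export]]
IntegerMatrix cpp_red_basin_grid(List params, double S, NumericMatrix attractors,
                                 NumericVector Zgrid, NumericVector MuGrid,
                                 double horizon = 400.0, double dt = 0.05,
                                 double match_logtol = 0.35) {
  RedPar q = unpack_red(params, S);
  int nZ = Zgrid.size(), nU = MuGrid.size(), nA = attractors.nrow();
  IntegerMatrix out(nZ, nU);
  std::vector<double> laZ(nA), laU(nA);
  for (int a = 0; a < nA; ++a) {
    laZ[a] = std::log(std::max(attractors(a, 0), 1.0));
    laU[a] = std::log(std::max(attractors(a, 1), 1.0));
  }
  auto nearest = [&](double Z, double mu, int& best) {
    double bestd = R_PosInf;
    double lz = std::log(std::max(Z, 1.0)), lu = std::log(std::max(mu, 1.0));
    best = 0;
    for (int a = 0; a < nA; ++a) {
      double d = std::max(std::fabs(lz - laZ[a]), std::fabs(lu - laU[a]));
      if (d < bestd) { bestd = d; best = a + 1; }
    }
    return bestd;
  };
  long chunk = 50, nsteps = (long)std::ceil(horizon / dt);
  for (int i = 0; i < nZ; ++i) {
    for (int j = 0; j < nU; ++j) {
      double Z = Zgrid[i], mu = MuGrid[j];
      int best = 0, hit = 0;
      // relax in short chunks; stop as soon as the trajectory is inside a
      // tight neighbourhood of one attractor (a conservative fraction of
      // the matching tolerance, so transits past a saddle do not count)
      for (long s = 0; s < nsteps; s += chunk) {
        red_relax(q, Z, mu, chunk * dt, dt);
        if (nearest(Z, mu, best) < 0.4 * match_logtol) { hit = best; break; }
      }
      if (!hit && nearest(Z, mu, best) < match_logtol) hit = best;
      out(i, j) = hit;
    }
  }
  return out;
}

static inline int grid_index(double v, double lo, double step, int n) {
  int k = (int)std::floor((std::log(std::max(v, 1.0)) - lo) / step);
  if (k < 0) k = 0;
  if (k >= n) k = n - 1;
  return k;
}

// Euler-Maruyama run with reflecting boundary at 0.  Uses R's RNG (seed with
// set.seed before calling).  Returns itinerary of basin labels (via the
// supplied basin grid), a visit histogram on the same grid, and a thinned
// trajectory.
// [[Rcpp::export]]
List cpp_red_em(List params, double S, double Z0, double mu0_state,
                double sigmaZ, double sigmaMu, double dt, double n_steps_d,
                NumericVector Zgrid, NumericVector MuGrid, IntegerMatrix basin,
                int thin = 100, bool multiplicative = true) {
  RedPar q = unpack_red(params, S);
  long n_steps = (long)n_steps_d;
  int nZ = Zgrid.size(), nU = MuGrid.size();
  double loZ = std::log(std::max(Zgrid[0], 1.0));
  double loU = std::log(std::max(MuGrid[0], 1.0));
  double stZ = (std::log(Zgrid[nZ - 1]) - loZ) / (nZ - 1);
  double stU = (std::log(MuGrid[nU - 1]) - loU) / (nU - 1);
  IntegerVector itin(n_steps + 1);
  NumericMatrix hist(nZ, nU);
  long ntraj = n_steps / thin + 1;
  NumericMatrix traj(ntraj, 2);
  double Z = Z0, mu = mu0_state;
  double sdt = std::sqrt(dt);
  RNGScope scope;
  long ti = 0;
  for (long s = 0; s <= n_steps; ++s) {
    int iz = grid_index(Z, loZ, stZ, nZ), iu = grid_index(mu, loU, stU, nU);
    itin[s] = basin(iz, iu);
    hist(iz, iu) += 1.0;
    if (s % thin == 0 && ti < ntraj) { traj(ti, 0) = Z; traj(ti, 1) = mu; ++ti; }
    if (s == n_steps) break;
    double dZ, dmu;
    red_drift(q, Z, mu, dZ, dmu);
    if (multiplicative) {
      // amplitude proportional to the current level (floored so the
      // boundary is not absorbing)
      Z += dZ * dt + sigmaZ * std::max(Z, 1.0) * sdt * norm_rand();
      mu += dmu * dt + sigmaMu * std::max(mu, 1.0) * sdt * norm_rand();
    } else {
      Z += dZ * dt + sigmaZ * sdt * norm_rand();
      mu += dmu * dt + sigmaMu * sdt * norm_rand();
    }
    if (Z < 0) Z = -Z;       // reflecting boundary
    if (mu < 0) mu = -mu;
  }
  return List::create(_["itinerary"] = itin, _["hist"] = hist,
                      _["traj"] = traj, _["final"] = NumericVector::create(Z, mu));
}
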