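#include <Rcpp.h>
using namespace Rcpp;

// Discretized Hamiltonian of a chiral filament on a cylinder of radius r
// (invr = 1/r, 0 for flat). Angles live on the N+1 nodes of N segments of
// length ds; the energy sums midpoint terms over segments.
static inline double junctionEnergy(const double *th, const double *ps, int j,
                                    double ds, double C, double K, double V,
                                    double k0, double w0, double invr) {
  const double thbar = 0.5 * (th[j] + th[j + 1]);
  const double psbar = 0.5 * (ps[j] + ps[j + 1]);
  const double dth = (th[j + 1] - th[j]) / ds;
  const double dps = (ps[j + 1] - ps[j]) / ds;
  const double st = std::sin(thbar);
  const double a = st * st * invr - k0;
  const double b = dps - 0.5 * std::sin(2.0 * thbar) * invr - w0;
  const double sp = std::sin(0.5 * psbar);
  return 0.5 * ds * (C * a * a + C * dth * dth + K * b * b + 2.0 * V * sp * sp);
}

static double totalEnergy(const std::vector<double> &th,
                          const std::vector<double> &ps, double ds, double C,
                          double K, double V, double k0, double w0,
                          double invr) {
  double e = 0.0;
  for (int j = 0; j + 1 < (int)th.size(); ++j)
    e += junctionEnergy(th.data(), ps.data(), j, ds, C, K, V, k0, w0, invr);
  return e;
}

// [[Rcpp::export(name = ".energyCpp")]]
double energyCpp(NumericVector theta, NumericVector psi, double ds, double C,
                 double K, double V, double k0, double w0, double invr) {
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> ps(psi.begin(), psi.end());
  return totalEnergy(th, ps, ds, C, K, V, k0, w0, invr);
}

// Analytic gradient of the discretized Hamiltonian w.r.t. all node angles,
// used by the deterministic quench. Layout: c(dE/dtheta, dE/dpsi).
// [[Rcpp::export(name = ".energyGradCpp")]]
NumericVector energyGradCpp(NumericVector theta, NumericVector psi, double ds,
                            double C, double K, double V, double k0, double w0,
                            double invr) {
  const int n = theta.size();
  NumericVector grad(2 * n);
  for (int j = 0; j + 1 < n; ++j) {
    const double thbar = 0.5 * (theta[j] + theta[j + 1]);
    const double psbar = 0.5 * (psi[j] + psi[j + 1]);
    const double dth = (theta[j + 1] - theta[j]) / ds;
    const double dps = (psi[j + 1] - psi[j]) / ds;
    const double st = std::sin(thbar);
    const double a = st * st * invr - k0;
    const double b = dps - 0.5 * std::sin(2.0 * thbar) * invr - w0;
    // d/dthbar of the two theta-dependent densities
    const double dA = 2.0 * C * a * std::sin(2.0 * thbar) * invr;
    const double dB = -2.0 * K * b * std::cos(2.0 * thbar) * invr;
    const double commonTh = 0.5 * ds * 0.5 * (dA + dB);
    const double gradDth = 0.5 * ds * 2.0 * C * dth / ds;
    grad[j] += commonTh - gradDth;
    grad[j + 1] += commonTh + gradDth;
    const double dV = 0.5 * ds * 2.0 * V * std::sin(0.5 * psbar) *
                      std::cos(0.5 * psbar) * 0.5;
    const double gradDps = 0.5 * ds * 2.0 * K * b / ds;
    grad[n + j] += dV - gradDps;
    grad[n + j + 1] += dV + gradDps;
  }
  return grad;
}

// Metropolis minimization (single run). Uses R's RNG so runs are fully
// reproducible from set.seed(). One node angle (theta or psi, probability
// 1/2 each) is perturbed per step by a uniform draw in [-amp, amp]; theta
// proposals leaving [0, pi] are rejected outright. The proposal amplitude
// is tuned toward 30-50% acceptance during the burn-in (first 10% of
// maxSteps, capped at 1e5 steps) and then frozen. Convergence: the
// minimized (best-visited) energy improves by less than tol * |E_best|
// over the previous `window` steps.
// [[Rcpp::export(name = ".metropolisCpp")]]
List metropolisCpp(NumericVector theta0, NumericVector psi0, double ds,
                   double C, double K, double V, double k0, double w0,
                   double invr, double maxSteps, double window, double tol,
                   double amp0, double temperature, int traceEvery) {
  const int n = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> ps(psi0.begin(), psi0.end());
  std::vector<double> bestTh = th, bestPs = ps;

  double E = totalEnergy(th, ps, ds, C, K, V, k0, w0, invr);
  double bestE = E;
  double amp = amp0;
  const double burnin = std::min(maxSteps * 0.1, 1e5);

  long accepted = 0, proposed = 0, tuneAcc = 0, tuneProp = 0;
  bool converged = false;
  double stepsUsed = 0;
  double winBest = bestE;
  long winCount = 0;

  std::vector<double> trace;
  trace.reserve((size_t)(maxSteps / traceEvery) + 2);
  trace.push_back(E);

  for (double step = 1; step <= maxSteps; ++step) {
    const int node = (int)(unif_rand() * n);
    const bool moveTheta = unif_rand() < 0.5;
    const double delta = (2.0 * unif_rand() - 1.0) * amp;
    ++proposed;
    ++tuneProp;

    bool reject = false;
    double oldVal, newVal;
    if (moveTheta) {
      oldVal = th[node];
      newVal = oldVal + delta;
      if (newVal < 0.0 || newVal > M_PI) reject = true;
    } else {
      oldVal = ps[node];
      newVal = oldVal + delta;
    }

    if (!reject) {
      double eOld = 0.0, eNew = 0.0;
      const int jlo = std::max(0, node - 1);
      const int jhi = std::min(n - 2, node);
      for (int j = jlo; j <= jhi; ++j)
        eOld += junctionEnergy(th.data(), ps.data(), j, ds, C, K, V, k0, w0, invr);
      if (moveTheta) th[node] = newVal; else ps[node] = newVal;
      for (int j = jlo; j <= jhi; ++j)
        eNew += junctionEnergy(th.data(), ps.data(), j, ds, C, K, V, k0, w0, invr);
      const double dE = eNew - eOld;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temperature)) {
        E += dE;
        ++accepted;
        ++tuneAcc;
        if (E < bestE) {
          bestE = E;
          bestTh = th;
          bestPs = ps;
        }
      } else {
        if (moveTheta) th[node] = oldVal; else ps[node] = oldVal;
      }
    }

    if (step <= burnin && tuneProp >= 1000) {
      const double acc = (double)tuneAcc / (double)tuneProp;
      if (acc > 0.5) amp *= 1.15; else if (acc < 0.3) amp *= 0.85;
      amp = std::min(1.5, std::max(1e-4, amp));
      tuneAcc = 0;
      tuneProp = 0;
    }

    if (((long)step) % traceEvery == 0) trace.push_back(E);

    if (step > burnin) {
      if (++winCount >= (long)window) {
        const double scale = std::max(std::fabs(bestE), 1e-3);
        if ((winBest - bestE) < tol * scale) {
          converged = true;
          stepsUsed = step;
          break;
        }
        winBest = bestE;
        winCount = 0;
      }
    }
  }
  if (!converged) stepsUsed = maxSteps;

  return List::create(
      _["theta"] = NumericVector(bestTh.begin(), bestTh.end()),
      _["psi"] = NumericVector(bestPs.begin(), bestPs.end()),
      _["energy"] = bestE,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = converged, _["steps"] = stepsUsed,
      _["acceptedFraction"] = proposed ? (double)accepted / proposed : 0.0,
      _["amplitude"] = amp);
}

// 8-connectivity connected-component labelling of a binary matrix
// (two-pass union-find). Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export(name = ".label8Cpp")]]
IntegerMatrix label8Cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto findRoot = [&](int x) {
    while (parent[x] != x) x = parent[x] = parent[parent[x]];
    return x;
  };
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int neigh[4], nn = 0;
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
        if (i > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i + 1 < nr && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        parent.push_back(++next);
        lab(i, j) = next;
      } else {
        int m = findRoot(neigh[0]);
        for (int k = 1; k < nn; ++k) m = std::min(m, findRoot(neigh[k]));
        lab(i, j) = m;
        for (int k = 0; k < nn; ++k) parent[findRoot(neigh[k])] = m;
      }
    }
  }
  std::vector<int> compact(next + 1, 0);
  int out = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j)) {
        const int r = findRoot(lab(i, j));
        if (!compact[r]) compact[r] = ++out;
        lab(i, j) = compact[r];
      }
  return lab;
}
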