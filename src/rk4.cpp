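// Fixed-step RK4 propagation of receptor-state occupancies driven by
// instantaneously rising, exponentially decaying glutamate transients
// (possibly a train of pulses) in the presence of a constant competitive
// antagonist. The generator is linear in the glutamate concentration:
// Q(t) = Q0 + L(t) * Qg, with the antagonist folded into Q0.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void matvec(const std::vector<double> &Q, int n,
                          const double *p, double *out) {
  for (int j = 0; j < n; ++j) out[j] = 0.0;
  for (int i = 0; i < n; ++i) {
    const double pi = p[i];
    if (pi == 0.0) continue;
    const double *row = &Q[(size_t)i * n];
    for (int j = 0; j < n; ++j) out[j] += pi * row[j];
  }
}

// [[Rcpp::export(name = ".rk4Occupancy")]]
List rk4Occupancy(NumericMatrix Q0in, NumericMatrix Qgin,
                  NumericVector onsets, double peak, double tau,
                  double dt, int nSteps, int stride, NumericVector p0in) {
  const int n = Q0in.nrow();
  std::vector<double> Q0((size_t)n * n), Qg((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      Q0[(size_t)i * n + j] = Q0in(i, j);
      Qg[(size_t)i * n + j] = Qgin(i, j);
    }
  auto ligand = [&](double t) -> double {
    double L = 0.0;
    for (int k = 0; k < onsets.size(); ++k)
      if (t >= onsets[k]) L += peak * std::exp(-(t - onsets[k]) / tau);
    return L;
  };
  std::vector<double> p(p0in.begin(), p0in.end());
  std::vector<double> Q((size_t)n * n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  auto assemble = [&](double L) {
    for (size_t k = 0; k < Q.size(); ++k) Q[k] = Q0[k] + L * Qg[k];
  };
  const int nRec = nSteps / stride + 1;
  NumericMatrix occ(nRec, n);
  for (int j = 0; j < n; ++j) occ(0, j) = p[j];
  double maxLeak = 0.0;
  for (int s = 1; s <= nSteps; ++s) {
    double t0 = (s - 1) * dt, tm = t0 + dt / 2, t1 = t0 + dt;
    assemble(ligand(t0)); matvec(Q, n, p.data(), k1.data());
    assemble(ligand(tm));
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + dt / 2 * k1[j];
    matvec(Q, n, tmp.data(), k2.data());
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + dt / 2 * k2[j];
    matvec(Q, n, tmp.data(), k3.data());
    assemble(ligand(t1));
    for (int j = 0; j < n; ++j) tmp[j] = p[j] + dt * k3[j];
    matvec(Q, n, tmp.data(), k4.data());
    double sum = 0.0;
    for (int j = 0; j < n; ++j) {
      p[j] += dt / 6 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
      sum += p[j];
    }
    double leak = std::fabs(sum - 1.0);
    if (leak > maxLeak) maxLeak = leak;
    if (leak > 1e-6)
      stop("probability leak %g at step %d; reduce the step size", leak, s);
    if (s % stride == 0)
      for (int j = 0; j < n; ++j) occ(s / stride, j) = p[j];
  }
  return List::create(_["occ"] = occ, _["maxLeak"] = maxLeak);
}
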