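// Backward-Euler integrator for a branched passive cable with K/Na leak,
// instantaneous Boltzmann Kir, event-driven double-exponential synapses and
// Ornstein-Uhlenbeck point-conductance noise.  The tree system is solved per
// step by Hines-ordered elimination (parents precede children).
//
// Units throughout: mV, ms, uS, nA, nF.  nF*mV/ms == uS*mV == nA.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cable_integrate(IntegerVector parent,   // 1-based, 0 at root
                     NumericVector cm,       // nF
                     NumericVector ga,       // uS axial conductance to parent
                     NumericVector gk,       // uS K leak
                     NumericVector gna,      // uS Na leak
                     NumericVector gkir,     // uS Kir maximal
                     double ek, double ena,
                     double kir_vhalf, double kir_k,
                     NumericMatrix syn,      // comp, onset, tau_r, tau_d, w, e_syn
                     NumericMatrix noise,    // comp, g0, sigma, tau, erev
                     int stim_comp,          // 1-based, 0 = none
                     NumericVector stim,     // nA during step k (length nsteps)
                     LogicalVector clamped,
                     NumericVector clamp_v,  // command at each sample (nsteps+1)
                     double dt, int nsteps,
                     NumericVector v0,
                     IntegerVector record,   // 1-based compartment indices
                     bool want_clamp_current) {
  const int n = parent.size();
  const int nsyn = syn.nrow();
  const int nnoise = noise.nrow();
  const int nrec = record.size();
  const bool any_clamp = is_true(any(clamped));

  std::vector<double> v(n), d(n), rhs(n), a(n), gkir_eff(n);
  std::vector<double> gsum(n), gesum(n); // synaptic+noise conductance, g*E sums
  for (int i = 0; i < n; ++i) v[i] = v0[i];

  // synapse state: impulse responses decaying with tau_r / tau_d
  std::vector<double> synA(nsyn, 0.0), synB(nsyn, 0.0), synNorm(nsyn), er(nsyn), ed(nsyn);
  std::vector<bool> fired(nsyn, false);
  for (int s = 0; s < nsyn; ++s) {
    double tr = syn(s, 2), td = syn(s, 3);
    double tp = tr * td / (td - tr) * std::log(td / tr);
    synNorm[s] = std::exp(-tp / td) - std::exp(-tp / tr);
    er[s] = std::exp(-dt / tr);
    ed[s] = std::exp(-dt / td);
  }

  std::vector<double> gn(nnoise), nA(nnoise), nB(nnoise);
  for (int q = 0; q < nnoise; ++q) {
    gn[q] = noise(q, 1);                       // start at mean g0
    double tau = noise(q, 3);
    nA[q] = std::exp(-dt / tau);
    nB[q] = noise(q, 2) * std::sqrt(1.0 - std::exp(-2.0 * dt / tau));
  }

  // Kir open fraction via a dense lookup table (NEURON-style TABLE):
  // 0.01 mV resolution over [-200, 100] mV, linear interpolation.
  const double tab_lo = -200.0, tab_hi = 100.0, tab_dv = 0.01;
  const int tab_n = (int)((tab_hi - tab_lo) / tab_dv) + 1;
  std::vector<double> mtab(tab_n);
  for (int j = 0; j < tab_n; ++j)
    mtab[j] = 1.0 / (1.0 + std::exp((tab_lo + j * tab_dv - kir_vhalf) / kir_k));
  auto kir_m = [&](double vv) {
    if (vv <= tab_lo) return mtab[0];
    if (vv >= tab_hi) return mtab[tab_n - 1];
    double x = (vv - tab_lo) / tab_dv;
    int j = (int)x;
    double w = x - j;
    return mtab[j] * (1.0 - w) + mtab[j + 1] * w;
  };

  NumericMatrix vout(nsteps + 1, nrec);
  NumericVector iclamp(want_clamp_current ? nsteps + 1 : 0);
  for (int r = 0; r < nrec; ++r) vout(0, r) = v[record[r] - 1];

  RNGScope scope; // noise draws come from R's RNG -> seed-reproducible

  for (int k = 0; k < nsteps; ++k) {
    double t_new = (k + 1) * dt;

    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);

    for (int s = 0; s < nsyn; ++s) {
      synA[s] *= er[s];
      synB[s] *= ed[s];
      if (!fired[s] && t_new >= syn(s, 1) - 1e-12) {
        double lag = t_new - syn(s, 1); // off-grid onsets handled exactly
        synA[s] += std::exp(-lag / syn(s, 2));
        synB[s] += std::exp(-lag / syn(s, 3));
        fired[s] = true;
      }
      double g = syn(s, 4) * (synB[s] - synA[s]) / synNorm[s];
      if (g < 0) g = 0;
      int c = (int)syn(s, 0) - 1;
      gsum[c] += g;
      gesum[c] += g * syn(s, 5);
    }

    for (int q = 0; q < nnoise; ++q) {
      double g0 = noise(q, 1);
      gn[q] = g0 + (gn[q] - g0) * nA[q] + nB[q] * norm_rand();
      if (gn[q] < 0) gn[q] = 0;
      int c = (int)noise(q, 0) - 1;
      gsum[c] += gn[q];
      gesum[c] += gn[q] * noise(q, 4);
    }

    for (int i = 0; i < n; ++i) {
      gkir_eff[i] = gkir[i] == 0.0 ? 0.0 : gkir[i] * kir_m(v[i]);
      double gtot = gk[i] + gna[i] + gkir_eff[i] + gsum[i];
      d[i] = cm[i] / dt + gtot;
      rhs[i] = cm[i] / dt * v[i] + gk[i] * ek + gna[i] * ena +
               gkir_eff[i] * ek + gesum[i];
      a[i] = 0.0;
    }
    if (stim_comp > 0) rhs[stim_comp - 1] += stim[k];

    for (int i = 1; i < n; ++i) { // axial coupling, off-diagonal = -ga
      int p = parent[i] - 1;
      d[i] += ga[i];
      d[p] += ga[i];
      a[i] = -ga[i];
    }

    double vc = any_clamp ? clamp_v[k + 1] : 0.0;
    if (any_clamp) {
      for (int i = 1; i < n; ++i) { // move known boundary values to RHS
        int p = parent[i] - 1;
        if (clamped[i] && !clamped[p]) { rhs[p] += ga[i] * vc; a[i] = 0.0; }
        if (!clamped[i] && clamped[p]) { rhs[i] += ga[i] * vc; a[i] = 0.0; }
        if (clamped[i] && clamped[p]) a[i] = 0.0;
      }
      for (int i = 0; i < n; ++i)
        if (clamped[i]) { d[i] = 1.0; rhs[i] = vc; }
    }

    for (int i = n - 1; i >= 1; --i) { // Hines elimination toward the root
      if (a[i] == 0.0) continue;
      int p = parent[i] - 1;
      double f = a[i] / d[i];
      d[p] -= a[i] * f;
      rhs[p] -= rhs[i] * f;
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i] - 1;
      v[i] = (rhs[i] - a[i] * v[p]) / d[i];
    }
    if (any_clamp)
      for (int i = 0; i < n; ++i)
        if (clamped[i]) v[i] = vc;

    if (!std::isfinite(v[0]))
      stop("integration diverged (non-finite voltage) at step %d", k + 1);

    if (want_clamp_current && any_clamp) {
      double ic = 0.0;
      double dvc = (clamp_v[k + 1] - clamp_v[k]) / dt;
      for (int i = 0; i < n; ++i) {
        if (!clamped[i]) continue;
        ic += gk[i] * (vc - ek) + gna[i] * (vc - ena) +
              gkir_eff[i] * (vc - ek) + gsum[i] * vc - gesum[i] +
              cm[i] * dvc;
      }
      for (int i = 1; i < n; ++i) {
        int p = parent[i] - 1;
        if (clamped[i] && !clamped[p]) ic += ga[i] * (vc - v[p]);
        if (!clamped[i] && clamped[p]) ic += ga[i] * (vc - v[i]);
      }
      iclamp[k + 1] = ic;
    }

    for (int r = 0; r < nrec; ++r) vout(k + 1, r) = v[record[r] - 1];
  }

  // final-state sanity: any non-finite voltage is an integration failure
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(v[i])) stop("integration diverged (non-finite voltage)");

  List out = List::create(_["v"] = vout);
  if (want_clamp_current) out["i_clamp"] = iclamp;
  return out;
}
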