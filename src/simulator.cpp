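#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo ensemble simulator for a network of exponential
// integrate-and-fire populations coupled by Poisson rate connections.
//
// Contract: every neuron of a target population receives an independent
// Poisson event stream whose rate is n_connections x (delayed source rate);
// each event jumps the membrane potential by the connection efficacy.
// Between events the potential follows the EIF drift. Crossing v_spike
// emits a spike, resets to v_reset and holds for the refractory time.
// Population rate output is spikes per sample bin / (ensemble x bin width).
//
// Connections arriving at the same target with the same efficacy are merged
// into one Poisson stream (superposition); per-connection delays are applied
// to the source rate before summation, so the merge is exact.

static inline double eif_drift_c(double v, const double* p) {
  // p: v_rest, delta_T, v_thres, tau
  double arg = (v - p[2]) / p[1];
  if (arg > 16.0) arg = 16.0;  // spike is imminent; cap to avoid overflow
  return (-(v - p[0]) + p[1] * std::exp(arg)) / p[3];
}

// [[Rcpp::export]]
List simulate_network_cpp(IntegerVector pop_n,
                          NumericMatrix pop_params,   // n_pop x 7
                          IntegerVector grp_target,   // 0-based
                          NumericVector grp_efficacy,
                          List grp_src_type,          // 0 = population, 1 = external
                          List grp_src_idx,           // 0-based
                          List grp_nconn,
                          List grp_delay,             // in steps
                          NumericMatrix ext_rates,    // (n_steps + 1) x n_ext, Hz
                          double dt,                  // ms
                          int n_steps,
                          int sample_every,
                          double smooth_tau,          // ms
                          IntegerVector density_steps) {
  const int n_pop = pop_n.size();
  const int n_grp = grp_target.size();
  const int n_samples = n_steps / sample_every;

  // per-population state
  std::vector< std::vector<double> > v(n_pop), jump(n_pop);
  std::vector< std::vector<int> > refr(n_pop);
  std::vector<int> tref_steps(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    v[p].assign(pop_n[p], pop_params(p, 0));        // start at v_rest
    jump[p].assign(pop_n[p], 0.0);
    refr[p].assign(pop_n[p], 0);
    tref_steps[p] = (int) std::ceil(pop_params(p, 6) / dt - 1e-9);
  }

  // smoothed instantaneous rate history, used for delayed delivery
  NumericMatrix hist(n_steps + 1, n_pop);
  NumericMatrix out(n_samples, n_pop);
  std::vector<double> smooth(n_pop, 0.0);
  std::vector<double> bin_count(n_pop, 0.0);

  std::vector<bool> want_density(n_steps + 1, false);
  for (int i = 0; i < density_steps.size(); ++i) {
    int s = density_steps[i];
    if (s >= 0 && s <= n_steps) want_density[s] = true;
  }
  List density;
  auto snapshot = [&](int step) {
    List pops(n_pop);
    for (int p = 0; p < n_pop; ++p) pops[p] = NumericVector(v[p].begin(), v[p].end());
    pops.attr("step") = step;
    density.push_back(pops);
  };
  if (want_density[0]) snapshot(0);

  const double alpha = (smooth_tau > 0.0) ? dt / smooth_tau : 1.0;

  for (int t = 0; t < n_steps; ++t) {
    // accumulate Poisson jumps per (target, efficacy) group
    for (int g = 0; g < n_grp; ++g) {
      IntegerVector st = grp_src_type[g];
      IntegerVector si = grp_src_idx[g];
      NumericVector nc = grp_nconn[g];
      IntegerVector dl = grp_delay[g];
      double rate_hz = 0.0;
      for (int s = 0; s < st.size(); ++s) {
        int td = t - dl[s];
        if (td < 0) continue;
        double r = (st[s] == 0) ? hist(td, si[s]) : ext_rates(td, si[s]);
        rate_hz += nc[s] * r;
      }
      double lambda = rate_hz * dt * 1e-3;
      if (lambda <= 0.0) continue;
      int tgt = grp_target[g];
      double eff = grp_efficacy[g];
      std::vector<double>& jt = jump[tgt];
      const int n = pop_n[tgt];
      for (int i = 0; i < n; ++i) {
        double k = R::rpois(lambda);
        if (k > 0.0) jt[i] += eff * k;
      }
    }

    // integrate and detect spikes
    for (int p = 0; p < n_pop; ++p) {
      double pv[7];
      for (int k = 0; k < 7; ++k) pv[k] = pop_params(p, k);
      const double v_spike = pv[4], v_reset = pv[5];
      const double v_floor = pv[0] - 40.0;
      int spikes = 0;
      std::vector<double>& vp = v[p];
      std::vector<double>& jp = jump[p];
      std::vector<int>& rp = refr[p];
      const int n = pop_n[p];
      for (int i = 0; i < n; ++i) {
        if (rp[i] > 0) { --rp[i]; vp[i] = v_reset; jp[i] = 0.0; continue; }
        double vi = vp[i] + jp[i];
        jp[i] = 0.0;
        vi += dt * eif_drift_c(vi, pv);
        if (vi >= v_spike) {
          ++spikes;
          vi = v_reset;
          rp[i] = tref_steps[p];
        } else if (vi < v_floor) {
          vi = v_floor;
        }
        vp[i] = vi;
      }
      double inst = spikes / (pop_n[p] * dt * 1e-3);  // Hz
      smooth[p] += alpha * (inst - smooth[p]);
      hist(t + 1, p) = smooth[p];
      bin_count[p] += spikes;
    }

    if ((t + 1) % sample_every == 0) {
      int b = (t + 1) / sample_every - 1;
      for (int p = 0; p < n_pop; ++p) {
        out(b, p) = bin_count[p] / (pop_n[p] * sample_every * dt * 1e-3);
        bin_count[p] = 0.0;
      }
    }
    if (want_density[t + 1]) snapshot(t + 1);
  }

  NumericVector times(n_samples);
  for (int b = 0; b < n_samples; ++b) times[b] = (b + 1) * sample_every * dt;

  return List::create(_["times"] = times,
                      _["rates"] = out,
                      _["smoothed"] = hist,
                      _["density"] = density);
}
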