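#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a reciprocally coupled pair of leaky
// integrate-and-fire neurons driven by exclusive and shared Poisson
// afferent populations. Afferent arrivals are delivered as instantaneous
// membrane-potential jumps (w_ex / w_inh per spike, W_r per partner
// spike); per step the number of arrivals on each branch is Poisson with
// mean N * lambda * dt, the common branch being drawn once and delivered
// to both neurons. Spike: V >= V_thr -> count++, V = V_reset. Partner
// coupling acts with a one-step delay. Uses R's RNG (seed with set.seed).
// [[Rcpp::export]]
IntegerMatrix lif_pair_counts(int n_trials, double trial_length_ms,
                              double dt_ms, double tau_ms, double e_rest,
                              double v_reset, double v_thr, double w_ex,
                              double w_inh, double w_r, int n_ex_excl,
                              int n_inh_excl, int n_ex_com, int n_inh_com,
                              double lam_ex, double lam_inh) {
  const int steps = (int)std::lround(trial_length_ms / dt_ms);
  const double dt_s = dt_ms / 1000.0;
  const double mu_e1 = n_ex_excl * lam_ex * dt_s;
  const double mu_i1 = n_inh_excl * lam_inh * dt_s;
  const double mu_ec = n_ex_com * lam_ex * dt_s;
  const double mu_ic = n_inh_com * lam_inh * dt_s;
  const double leak = dt_ms / tau_ms;
  IntegerMatrix counts(n_trials, 2);
  for (int tr = 0; tr < n_trials; ++tr) {
    double v1 = e_rest, v2 = e_rest;
    bool sp1 = false, sp2 = false;
    int c1 = 0, c2 = 0;
    for (int s = 0; s < steps; ++s) {
      double ec = R::rpois(mu_ec), ic = R::rpois(mu_ic);
      double e1 = R::rpois(mu_e1), i1 = R::rpois(mu_i1);
      double e2 = R::rpois(mu_e1), i2 = R::rpois(mu_i1);
      v1 += leak * (e_rest - v1) + w_ex * (e1 + ec) + w_inh * (i1 + ic) +
            (sp2 ? w_r : 0.0);
      v2 += leak * (e_rest - v2) + w_ex * (e2 + ec) + w_inh * (i2 + ic) +
            (sp1 ? w_r : 0.0);
      if (!std::isfinite(v1) || !std::isfinite(v2))
        stop("non-finite membrane potential (check dt / parameters)");
      sp1 = v1 >= v_thr;
      sp2 = v2 >= v_thr;
      if (sp1) { ++c1; v1 = v_reset; }
      if (sp2) { ++c2; v2 = v_reset; }
    }
    counts(tr, 0) = c1;
    counts(tr, 1) = c2;
  }
  return counts;
}

// Analytic-check helper: free membrane relaxation (no input, no spiking),
// returning the Euler-integrated V(t) trace from v0.
// [[Rcpp::export]]
NumericVector lif_relax_trace(double v0, double e_rest, double tau_ms,
                              double dt_ms, int steps) {
  NumericVector v(steps + 1);
  v[0] = v0;
  const double leak = dt_ms / tau_ms;
  for (int s = 0; s < steps; ++s) v[s + 1] = v[s] + leak * (e_rest - v[s]);
  return v;
}
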