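#include <Rcpp.h>
using namespace Rcpp;

// Event-driven update of a conductance-based LIF network.
//
// The connectome is passed in compressed-sparse-column layout with the
// column index giving the PRESYNAPTIC neuron, so that the targets of a
// spiking cell are contiguous. Weights are signed by source type
// (inhibitory sources carry negative entries); the gating sums kept per
// neuron are
//   x_ampa  : sum_j w_j s_j^AMPA(t)   over recurrent excitatory afferents
//   x_gaba  : sum_j w_j s_j^GABA(t)   over inhibitory afferents (w > 0)
//   x_ext   : s_ext^AMPA(t)           background Poisson drive, unit weight
// each obeying ds/dt = -s/tau + sum_k delta(t - t_k), integrated with a
// forward Euler step matching the membrane update.
//
// Synaptic currents (driving forces chosen so that AMPA depolarizes and
// GABA pulls the membrane toward V_I = V_rest):
//   I_AMPA = g_AMPA (V_E - V) (x_ampa + x_ext)
//   I_GABA = g_GABA (V_I - V) x_gaba
//
// `gain_edge` flags inter-areal synapses whose weight is multiplied by a
// piecewise-constant gain g(t) (used for state-scaled sessions; gain = 1
// reproduces the static network).
//
// Uses the R RNG (seed via set.seed() before calling).

// [[Rcpp::export(name = ".sim_lif_cpp")]]
List sim_lif_cpp(IntegerVector Wi, IntegerVector Wp, NumericVector Wx,
                 LogicalVector edge_scaled,
                 NumericVector Cm, NumericVector gL, NumericVector Vrest,
                 NumericVector Vth, NumericVector tref_ms,
                 NumericVector u_bkgnd_hz,
                 double tau_ampa_ms, double tau_gaba_ms,
                 double v_e, NumericVector v_i,
                 double g_ampa, double g_gaba,
                 double dt_ms, double duration_s,
                 NumericVector stim_amp_pa, double stim_on_s, double stim_off_s,
                 NumericVector gain_t_s, NumericVector gain_val,
                 NumericVector v0) {
  const int n = Cm.size();
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt_ms);
  const double dt_s = dt_ms / 1000.0;
  const double dec_a = 1.0 - dt_ms / tau_ampa_ms;
  const double dec_g = 1.0 - dt_ms / tau_gaba_ms;
  if (dec_a <= 0.0 || dec_g <= 0.0)
    stop("integration step must be smaller than the synaptic time constants");

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> x_ampa(n, 0.0), x_gaba(n, 0.0), x_ext(n, 0.0);
  std::vector<int> ref_left(n, 0);
  std::vector<int> ref_steps(n);
  std::vector<double> rate_dt(n);
  for (int i = 0; i < n; ++i) {
    ref_steps[i] = (int)std::lround(tref_ms[i] / dt_ms);
    rate_dt[i] = u_bkgnd_hz[i] * dt_s;
  }

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const long stim_a = (long)std::llround(stim_on_s * 1000.0 / dt_ms);
  const long stim_b = (long)std::llround(stim_off_s * 1000.0 / dt_ms);
  int gain_idx = 0;
  const int n_gain = gain_t_s.size();

  RNGScope scope;
  for (long step = 0; step < n_steps; ++step) {
    const double t_now = step * dt_s;
    while (gain_idx + 1 < n_gain && gain_t_s[gain_idx + 1] <= t_now) ++gain_idx;
    const double gain = n_gain > 0 ? gain_val[gain_idx] : 1.0;
    const bool stim_on = (step >= stim_a && step < stim_b);

    for (int i = 0; i < n; ++i) {
      // background Poisson events enter the external gating sum with unit
      // increment per event
      if (rate_dt[i] > 0.0) {
        double k = R::rpois(rate_dt[i]);
        if (k > 0.0) x_ext[i] += k;
      }
      if (ref_left[i] > 0) {
        --ref_left[i];
        V[i] = Vrest[i];
        continue;
      }
      const double i_ampa = g_ampa * (v_e - V[i]) * (x_ampa[i] + x_ext[i]);
      const double i_gaba = g_gaba * (v_i[i] - V[i]) * x_gaba[i];
      double i_syn = i_ampa + i_gaba;
      if (stim_on) i_syn += stim_amp_pa[i];
      V[i] += dt_ms / Cm[i] * (-gL[i] * (V[i] - Vrest[i]) + i_syn);
      if (!std::isfinite(V[i]))
        stop("membrane potential diverged (neuron %d, step %ld); "
             "reduce coupling or the integration step", i + 1, step + 1);
    }

    // spike detection at end of step, then reset + refractory clamp
    for (int j = 0; j < n; ++j) {
      if (ref_left[j] == 0 && V[j] >= Vth[j]) {
        sp_id.push_back(j + 1);
        sp_t.push_back((step + 1) * dt_s);
        V[j] = Vrest[j];
        ref_left[j] = ref_steps[j];
        for (int e = Wp[j]; e < Wp[j + 1]; ++e) {
          const int tgt = Wi[e];
          double w = Wx[e];
          if (edge_scaled[e]) w *= gain;
          if (w >= 0.0) x_ampa[tgt] += w; else x_gaba[tgt] -= w;
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      x_ampa[i] *= dec_a;
      x_gaba[i] *= dec_g;
      x_ext[i] *= dec_a;
    }
  }

  return List::create(_["unit_id"] = wrap(sp_id), _["time_s"] = wrap(sp_t),
                      _["v_final"] = wrap(V));
}
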