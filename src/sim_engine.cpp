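#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based exponential-synapse LIF network, fixed step dt.
//
//   C_m dV/dt = -(C_m/tau_m)(V - E_L) + I_e + g_e (E_e - V) + g_i (E_i - V)
//
// Conductances decay exactly (factor exp(-dt/tau) per step); the membrane is
// advanced by exponential Euler with the conductances held constant over the
// step.  Threshold is detected at step boundaries; a spike is stamped at the
// end-of-step time, V is reset to V_r and clamped there for the refractory
// period.  Parrot neurons (type_idx == -1) emit exactly the imposed stimulus
// steps.  Delayed spike arrival adds |w| to the conductance channel selected
// by the sign of w, via a ring buffer of future increments.
//
// Synapses are in CSR layout keyed by the pre-synaptic neuron.  All indices
// are 0-based; delays are in integer steps (>= 1).
// [[Rcpp::export]]
List sim_engine_cpp(IntegerVector type_idx,
                    NumericVector C_m, NumericVector tau_m, NumericVector E_L,
                    NumericVector t_ref, NumericVector I_e, NumericVector V_r,
                    NumericVector V_th, NumericVector tau_exc,
                    NumericVector tau_inh,
                    IntegerVector syn_ptr, IntegerVector syn_post,
                    NumericVector syn_w, IntegerVector syn_delay,
                    IntegerVector stim_ptr, IntegerVector stim_step,
                    NumericVector stim_time,
                    double dt, double E_exc, double E_inh, int n_steps) {
  int n = type_idx.size();
  int ntypes = C_m.size();

  std::vector<double> dec_e(ntypes), dec_i(ntypes), g_L(ntypes);
  std::vector<int> ref_steps(ntypes);
  for (int k = 0; k < ntypes; ++k) {
    dec_e[k] = std::exp(-dt / tau_exc[k]);
    dec_i[k] = std::exp(-dt / tau_inh[k]);
    g_L[k] = C_m[k] / tau_m[k];
    ref_steps[k] = (int)std::lround(t_ref[k] / dt);
  }

  std::vector<double> V(n), ge(n, 0.0), gi(n, 0.0);
  std::vector<int> refr(n, 0);
  for (int i = 0; i < n; ++i)
    V[i] = (type_idx[i] >= 0) ? E_L[type_idx[i]] : 0.0;

  int max_delay = 1;
  for (int s = 0; s < syn_delay.size(); ++s)
    if (syn_delay[s] > max_delay) max_delay = syn_delay[s];
  int R = max_delay + 1;
  std::vector<double> ring_e((size_t)R * n, 0.0), ring_i((size_t)R * n, 0.0);

  std::vector<int> stim_pos(n);
  for (int i = 0; i < n; ++i) stim_pos[i] = stim_ptr[i];

  std::vector<int> out_id;
  std::vector<double> out_t;
  out_id.reserve(1 << 16);
  out_t.reserve(1 << 16);

  std::vector<int> fired;
  fired.reserve(1024);

  for (int t = 0; t < n_steps; ++t) {
    int slot = t % R;
    double* arr_e = &ring_e[(size_t)slot * n];
    double* arr_i = &ring_i[(size_t)slot * n];
    fired.clear();

    for (int i = 0; i < n; ++i) {
      int k = type_idx[i];
      if (k < 0) {  // parrot relay
        if (stim_pos[i] < stim_ptr[i + 1] && stim_step[stim_pos[i]] == t) {
          fired.push_back(i);
          out_id.push_back(i);
          out_t.push_back(stim_time[stim_pos[i]]);  // parrot: relay verbatim
          ++stim_pos[i];
        }
        continue;
      }
      // conductance decay, then arrivals for this step
      ge[i] = ge[i] * dec_e[k] + arr_e[i];
      gi[i] = gi[i] * dec_i[k] + arr_i[i];
      arr_e[i] = 0.0; arr_i[i] = 0.0;

      if (refr[i] > 0) { --refr[i]; V[i] = V_r[k]; continue; }

      double gt = g_L[k] + ge[i] + gi[i];
      double vinf = (g_L[k] * E_L[k] + I_e[k] + ge[i] * E_exc + gi[i] * E_inh) / gt;
      V[i] = vinf + (V[i] - vinf) * std::exp(-dt * gt / C_m[k]);
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at neuron %d, step %d", i + 1, t);

      if (V[i] >= V_th[k]) {
        fired.push_back(i);
        out_id.push_back(i);
        out_t.push_back((t + 1) * dt);
        V[i] = V_r[k];
        refr[i] = ref_steps[k];
      }
    }

    // fan out the spikes of this step
    for (size_t f = 0; f < fired.size(); ++f) {
      int i = fired[f];
      for (int s = syn_ptr[i]; s < syn_ptr[i + 1]; ++s) {
        int tgt = syn_post[s];
        int dslot = (t + syn_delay[s]) % R;
        if (syn_w[s] >= 0)
          ring_e[(size_t)dslot * n + tgt] += syn_w[s];
        else
          ring_i[(size_t)dslot * n + tgt] -= syn_w[s];
      }
    }
  }

  return List::create(_["id"] = wrap(out_id), _["t"] = wrap(out_t));
}
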