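#include <Rcpp.h>
using namespace Rcpp;

// Feed-forward experiment: N presynaptic Poisson neurons at rate fn (per
// ms), each through its own Tsodyks-Markram synapse, drive a leaky
// integrate-and-fire neuron with an adaptive firing threshold.
//
// Synapses are updated event-driven: per step the number of firing
// synapses is Binomial(N, fn*dt); each firing synapse first relaxes its
// (x, u) analytically over the time since its previous spike, then
// releases u*x (pre-facilitation u) and jumps u by U*(1-u). Active
// transmitter is pooled in one variable Y since tau_in is shared.
//
// Membrane: tau_m dV/dt = -V + R * (I_syn + S(t)); threshold:
// tau_th dth/dt = theta0 + k * R * I_lp - th, with I_lp a slow low-pass
// of the synaptic current, so the mean distance to threshold stays near
// theta0 as the presynaptic rate varies.
//
// mode: 0 = static (x=1, u=U), 1 = dynamic, 2 = depression-only (u=1).
// [[Rcpp::export]]
List sr_simulate_cpp(int N, double fn, double dt, int n_steps,
                     double U, double tau_rec, double tau_fac,
                     double tau_in, double A, int mode,
                     NumericVector signal,
                     double tau_m, double R, double v_reset,
                     double theta0, double k_adapt, double tau_th,
                     double tau_lp, int refrac_steps,
                     double lp_init, double x_init, double u_init) {
  std::vector<double> x(N, x_init), u(N, (mode == 2) ? 1.0 : u_init);
  std::vector<double> last(N, 0.0);  // step of previous spike per synapse
  double Y = 0.0;
  double V = 0.0, th = theta0 + k_adapt * R * lp_init, I_lp = lp_init;
  double p_fire = fn * dt;
  double decay_y = std::exp(-dt / tau_in);
  int refrac = 0;
  std::vector<int> spike_steps;
  std::vector<int> idx(N);
  for (int jn = 0; jn < N; ++jn) idx[jn] = jn;
  NumericVector I_trace(n_steps);
  double clip_count = 0.0;
  for (int t = 0; t < n_steps; ++t) {
    double release = 0.0;
    int k = (p_fire > 0.0) ? (int)R::rbinom((double)N, p_fire) : 0;
    // partial Fisher-Yates: k distinct firing synapses
    for (int s = 0; s < k; ++s) {
      int pick = s + (int)(unif_rand() * (N - s));
      if (pick >= N) pick = N - 1;
      std::swap(idx[s], idx[pick]);
      int jn = idx[s];
      if (mode != 0) {
        double gap = (t - last[jn]) * dt;
        x[jn] = 1.0 - (1.0 - x[jn]) * std::exp(-gap / tau_rec);
        if (mode == 1 && tau_fac > 0.0)
          u[jn] = U + (u[jn] - U) * std::exp(-gap / tau_fac);
        last[jn] = t;
      }
      double rel = u[jn] * x[jn];
      release += rel;
      if (mode != 0) {
        x[jn] -= rel;
        if (mode == 1 && tau_fac > 0.0) u[jn] += U * (1.0 - u[jn]);
        if (x[jn] < 0.0) { x[jn] = 0.0; clip_count += 1.0; }
        if (u[jn] > 1.0) { u[jn] = 1.0; clip_count += 1.0; }
      }
    }
    Y = Y * decay_y + release;
    // midpoint correction: arrivals count half on their own step, so the
    // sampled mean matches the continuous-time average of the pulse train
    double I = A * (Y - 0.5 * release);
    I_trace[t] = I;
    I_lp += dt * (I - I_lp) / tau_lp;
    th += dt * (theta0 + k_adapt * R * I_lp - th) / tau_th;
    double I_tot = I + signal[t];
    V += dt * (-V + R * I_tot) / tau_m;
    if (refrac > 0) {
      --refrac;
    } else if (V >= th) {
      spike_steps.push_back(t);
      V = v_reset;
      refrac = refrac_steps;
    }
  }
  return List::create(_["spike_steps"] = wrap(spike_steps),
                      _["I_trace"] = I_trace,
                      _["clipped"] = clip_count,
                      _["final_threshold"] = th);
}
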