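#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the bistable rate model
//   tau_nu dnu/dt = -nu + nu_m * S(J nu x - theta) + zeta(t)
//   dx/dt = (1 - x)/tau_r - U x nu + (D/tau_r) xi(t)
// with S(X) = 1/(1 + exp(-X/delta)). Time in tau_nu units; nu clipped to
// [0, Inf), x to [0, 1] (clip events counted). Trajectory thinned by
// `thin` for output.
// [[Rcpp::export]]
List ud_simulate_cpp(double nu0, double x0, int n_steps, double dt,
                     double nu_m, double J, double theta, double delta,
                     double tau_r, double U, double D, double sigma_nu,
                     int thin) {
  int n_out = n_steps / thin + 1;
  NumericVector nu_out(n_out), x_out(n_out), t_out(n_out);
  double nu = nu0, x = x0;
  double sq_dt = std::sqrt(dt);
  double amp_x = (tau_r > 0.0) ? (D / tau_r) * sq_dt : 0.0;
  double amp_nu = sigma_nu * sq_dt;
  long clipped = 0;
  int j = 0;
  nu_out[0] = nu; x_out[0] = x; t_out[0] = 0.0;
  j = 1;
  for (int i = 1; i <= n_steps; ++i) {
    double X = (J * nu * x - theta) / delta;
    double S = 1.0 / (1.0 + std::exp(-X));
    double nu_new = nu + dt * (-nu + nu_m * S);
    if (amp_nu > 0.0) nu_new += amp_nu * norm_rand();
    double x_new = x + dt * ((1.0 - x) / tau_r - U * x * nu);
    if (amp_x > 0.0) x_new += amp_x * norm_rand();
    if (nu_new < 0.0) { nu_new = 0.0; ++clipped; }
    if (x_new < 0.0) { x_new = 0.0; ++clipped; }
    if (x_new > 1.0) { x_new = 1.0; ++clipped; }
    nu = nu_new; x = x_new;
    if (i % thin == 0 && j < n_out) {
      nu_out[j] = nu; x_out[j] = x; t_out[j] = i * dt; ++j;
    }
  }
  return List::create(_["t"] = t_out, _["nu"] = nu_out, _["x"] = x_out,
                      _["clipped"] = (double)clipped);
}
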