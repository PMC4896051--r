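// Euler-Maruyama simulation of the calcium-based bistable synapse model.
//
// The synaptic efficacy rho follows
//
//   tau * drho/dt = -rho(1-rho)(rho_star-rho)
//                   + gamma_p (1-rho) H[c(t)-theta_p]
//                   - gamma_d rho     H[c(t)-theta_d]
//                   + sigma sqrt(tau) sqrt(H[c-theta_p]+H[c-theta_d]) eta(t)
//
// with H the Heaviside function and eta unit white noise, i.e. noise is
// active only while calcium sits above at least one threshold.  Calcium
// is the exact superposition of exponentially decaying transients
// (jump by the event amplitude, decay with time constant tau_ca), so it
// is propagated analytically between grid points.
//
// Performance: while c < theta_d both Heaviside terms and the noise are
// off, so the dynamics are the deterministic cubic drift only; those
// stretches are integrated with a coarse step (tau/500) instead of the
// fine calcium-resolving step (tau_ca/100 by default).
//
// Uses R's RNG (norm_rand) so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double cubic_drift(double rho, double rho_star, double tau) {
  return -rho * (1.0 - rho) * (rho_star - rho) / tau;
}

// [[Rcpp::export(name = ".gb_simulate_cpp")]]
NumericVector gb_simulate_cpp(NumericVector event_times, NumericVector event_amps,
                              double t_total, double tau_ca, double tau,
                              double gamma_p, double gamma_d, double sigma,
                              double theta_p, double theta_d, double rho_star,
                              double rho0, int n_trials, double dt_fine,
                              double dt_coarse) {
  const int n_ev = event_times.size();
  NumericVector out(n_trials);
  const double sq_tau = std::sqrt(tau);

  for (int trial = 0; trial < n_trials; trial++) {
    double t = 0.0, c = 0.0, rho = rho0;
    int idx = 0;
    while (t < t_total - 1e-12) {
      // deliver any events due at the current time
      while (idx < n_ev && event_times[idx] <= t + 1e-12) {
        c += event_amps[idx];
        idx++;
      }
      double t_next = (idx < n_ev && event_times[idx] < t_total)
                          ? event_times[idx] : t_total;
      if (c < theta_d) {
        // silent: noise off, thresholds off -> deterministic cubic only
        double h = std::min(dt_coarse, t_next - t);
        rho += cubic_drift(rho, rho_star, tau) * h;
        c *= std::exp(-h / tau_ca);
        t += h;
      } else {
        double h = std::min(dt_fine, t_next - t);
        bool up_p = c >= theta_p, up_d = c >= theta_d;
        double drift = cubic_drift(rho, rho_star, tau);
        if (up_p) drift += gamma_p * (1.0 - rho) / tau;
        if (up_d) drift -= gamma_d * rho / tau;
        double namp = sigma * std::sqrt((double)(up_p + up_d)) / sq_tau;
        rho += drift * h + namp * std::sqrt(h) * norm_rand();
        c *= std::exp(-h / tau_ca);
        t += h;
      }
    }
    out[trial] = rho;
  }
  return out;
}
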