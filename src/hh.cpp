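// Single-compartment Hodgkin-Huxley integrator.
//
// Classic squid-axon kinetics with voltages shifted so that the resting
// potential sits near -65 mV (the convention of the default "hh" mechanism
// in common simulators).  Units follow the usual electrophysiology
// conventions: mV, ms, nA, uF cm-2, S cm-2.  Internally the membrane
// equation is
//
//   cm * dv/dt = 1000 * ( -gnabar*m^3*h*(v-ena) - gkbar*n^4*(v-ek)
//                         - gl*(v-el) + i_inj/area )
//
// where currents are in mA cm-2 (S cm-2 * mV), cm in uF cm-2 and the
// factor 1000 converts (mA cm-2)/(uF cm-2) = V/s into mV/ms.
// Gating kinetics are scaled by q10 = 3^((celsius-6.3)/10).

#include <Rcpp.h>
using namespace Rcpp;

static inline double alpha_m(double v) {
  double x = v + 40.0;
  // limit of 0.1*x/(1-exp(-x/10)) as x -> 0
  return std::fabs(x) < 1e-9 ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 55.0;
  return std::fabs(x) < 1e-9 ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

struct HHParams {
  double cm, area, gnabar, gkbar, gl, ena, ek, el, q10;
};

static inline void hh_deriv(const double *s, double i_nA, const HHParams &p,
                            double *d) {
  double v = s[0], m = s[1], h = s[2], n = s[3];
  double ina = p.gnabar * m * m * m * h * (v - p.ena);
  double ik  = p.gkbar * n * n * n * n * (v - p.ek);
  double il  = p.gl * (v - p.el);
  // i_nA * 1e-6 converts nA to mA; /area gives mA cm-2
  d[0] = 1000.0 * (-(ina + ik + il) + i_nA * 1e-6 / p.area) / p.cm;
  d[1] = p.q10 * (alpha_m(v) * (1.0 - m) - beta_m(v) * m);
  d[2] = p.q10 * (alpha_h(v) * (1.0 - h) - beta_h(v) * h);
  d[3] = p.q10 * (alpha_n(v) * (1.0 - n) - beta_n(v) * n);
}

// [[Rcpp::export(name = ".hh_integrate_cpp")]]
List hh_integrate_cpp(double cm, double area_cm2, double gnabar, double gkbar,
                      double gl, double ena, double ek, double el,
                      double v_init, double celsius, double amp_nA,
                      double delay, double duration, double total,
                      double holding_nA, double dt, double record_dt) {
  HHParams p;
  p.cm = cm; p.area = area_cm2; p.gnabar = gnabar; p.gkbar = gkbar;
  p.gl = gl; p.ena = ena; p.ek = ek; p.el = el;
  p.q10 = std::pow(3.0, (celsius - 6.3) / 10.0);

  double s[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  s[0] = v_init;
  s[1] = alpha_m(v_init) / (alpha_m(v_init) + beta_m(v_init));
  s[2] = alpha_h(v_init) / (alpha_h(v_init) + beta_h(v_init));
  s[3] = alpha_n(v_init) / (alpha_n(v_init) + beta_n(v_init));

  long nstep = (long)std::llround(total / dt);
  long rec_every = (long)std::llround(record_dt / dt);
  if (rec_every < 1) rec_every = 1;
  long nrec = nstep / rec_every;

  NumericVector tv(nrec + 1), vv(nrec + 1);
  tv[0] = 0.0; vv[0] = s[0];
  long ri = 1;

  for (long k = 0; k < nstep; k++) {
    double t = k * dt;
    double t1 = t + dt;
    // the injected current is piecewise constant; evaluating it at the
    // step midpoint and holding it for all four stages integrates each
    // constant piece exactly (pulse edges coincide with step boundaries
    // whenever dt divides delay/duration) and preserves the RK4 order
    double th = t + 0.5 * dt;
    double ii = holding_nA + ((th >= delay && th < delay + duration) ? amp_nA : 0.0);

    hh_deriv(s, ii, p, k1);
    for (int j = 0; j < 4; j++) tmp[j] = s[j] + 0.5 * dt * k1[j];
    hh_deriv(tmp, ii, p, k2);
    for (int j = 0; j < 4; j++) tmp[j] = s[j] + 0.5 * dt * k2[j];
    hh_deriv(tmp, ii, p, k3);
    for (int j = 0; j < 4; j++) tmp[j] = s[j] + dt * k3[j];
    hh_deriv(tmp, ii, p, k4);
    for (int j = 0; j < 4; j++)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (!std::isfinite(s[0]))
      stop("non-finite membrane potential at t = %f ms (diverged integration)", t1);

    if ((k + 1) % rec_every == 0 && ri <= nrec) {
      tv[ri] = t1;
      vv[ri] = s[0];
      ri++;
    }
  }
  return List::create(_["t"] = tv, _["v"] = vv);
}
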