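#include <Rcpp.h>
using namespace Rcpp;

// Multi-cycle classical RK4 for the scalar linear ODE  y'(t) = f(t) - y/tau
// on one cardiac period discretized into n fixed steps of size h.
//
// Both directions of the three-element Windkessel reduce to this form:
//   forward  (flow -> pressure): y = capacitor pressure Pc, f = Q/C, tau = R2*C
//   inverse  (pressure -> flow): y = Q, f = (C*dP/dt + P/R2)/(R1*C),
//                                tau = R1*R2*C/(R1+R2)
//
// `fhalf` holds f sampled at half-step resolution: fhalf[j] = f(j*h/2),
// j = 0..2n, with fhalf[2n] the periodic wrap value f(T) = f(0).
// Cycles repeat from the endpoint of the previous cycle until the max-norm
// relative change between consecutive cycle traces drops below `tol`.
//
// [[Rcpp::export(name = ".wk_integrate_cycles")]]
List wk_integrate_cycles(NumericVector fhalf, double tau, double h,
                         double y0, int max_cycles, double tol) {
  int n = (fhalf.size() - 1) / 2;
  if (2 * n + 1 != fhalf.size())
    stop("fhalf must have odd length 2n+1");
  if (tau <= 0 || h <= 0)
    stop("tau and h must be positive");

  NumericVector prev(n + 1), cur(n + 1);
  double y = y0;
  double resid = NA_REAL;
  bool converged = false;
  int cycles_run = 0;

  for (int cycle = 1; cycle <= max_cycles; ++cycle) {
    cycles_run = cycle;
    cur[0] = y;
    for (int i = 0; i < n; ++i) {
      const double f0 = fhalf[2 * i];
      const double fm = fhalf[2 * i + 1];
      const double f1 = fhalf[2 * i + 2];
      const double k1 = f0 - y / tau;
      const double k2 = fm - (y + 0.5 * h * k1) / tau;
      const double k3 = fm - (y + 0.5 * h * k2) / tau;
      const double k4 = f1 - (y + h * k3) / tau;
      y += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      cur[i + 1] = y;
    }
    if (cycle > 1) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i <= n; ++i) {
        num = std::max(num, std::fabs(cur[i] - prev[i]));
        den = std::max(den, std::fabs(cur[i]));
      }
      resid = den > 0.0 ? num / den : num;
      if (resid < tol) { converged = true; break; }
    }
    std::copy(cur.begin(), cur.end(), prev.begin());
  }

  return List::create(_["y"] = cur,
                      _["cycles"] = cycles_run,
                      _["residual"] = resid,
                      _["converged"] = converged);
}
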