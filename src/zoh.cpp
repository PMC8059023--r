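#include <Rcpp.h>
using namespace Rcpp;

// Zero-initial-state response of gain/(tau s + 1) to a zero-order-hold input
// sampled with period dt. Exact discretisation: x[k] = a x[k-1] + (1-a) u[k-1],
// a = exp(-dt/tau).
// [[Rcpp::export]]
NumericVector zoh_first_order(NumericVector u, double dt, double gain, double tau) {
  int n = u.size();
  NumericVector y(n);
  double a = std::exp(-dt / tau), b = 1.0 - a, x = 0.0;
  if (n == 0) return y;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    x = a * x + b * u[i - 1];
    y[i] = gain * x;
  }
  return y;
}

// Zero-initial-state ZOH response of gain/((tau1 s + 1)(tau2 s + 1)).
// Distinct poles use the modal (partial-fraction) form; near-coincident
// poles (relative gap < 1e-8, where the modal difference would cancel
// catastrophically) switch to the confluent double-pole closed form.
// [[Rcpp::export]]
NumericVector zoh_second_order(NumericVector u, double dt, double gain,
                               double tau1, double tau2) {
  int n = u.size();
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = 0.0;
  if (std::abs(tau1 - tau2) < 1e-8 * (tau1 + tau2)) {
    double tau = std::sqrt(tau1 * tau2), p = 1.0 / tau;
    double a = std::exp(-p * dt);
    double b2 = (1.0 - a) / p;
    double b1 = (1.0 - a * (1.0 + p * dt)) / (p * p);
    double c = gain * p * p;
    double x1 = 0.0, x2 = 0.0;
    for (int i = 1; i < n; ++i) {
      double x1n = a * x1 + a * dt * x2 + b1 * u[i - 1];
      x2 = a * x2 + b2 * u[i - 1];
      x1 = x1n;
      y[i] = c * x1;
    }
  } else {
    double p1 = 1.0 / tau1, p2 = 1.0 / tau2;
    double a1 = std::exp(-p1 * dt), a2 = std::exp(-p2 * dt);
    double b1 = (1.0 - a1) / p1, b2 = (1.0 - a2) / p2;
    double c = gain / (tau1 - tau2);
    double x1 = 0.0, x2 = 0.0;
    for (int i = 1; i < n; ++i) {
      x1 = a1 * x1 + b1 * u[i - 1];
      x2 = a2 * x2 + b2 * u[i - 1];
      y[i] = c * (x1 - x2);
    }
  }
  return y;
}
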