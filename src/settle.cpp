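#include <Rcpp.h>
using namespace Rcpp;

// Settle a ring layer's rate code from a fixed excitatory drive under pooled
// FFFB inhibition. Mirrors the documented dynamics: per cycle the feedback
// term is exponentially averaged, the pooled inhibition raises the threshold
// conductance linearly (ge_theta = a*gi + b), and activations step halfway
// toward the thresholded saturating rate. Early-stops when the largest
// activity change falls below tol.
// [[Rcpp::export(name = ".settle_ge_core")]]
List settle_ge_core(NumericVector ge, double gbar_e, double gamma,
                    double a, double b, double Gi, double ff,
                    double fb_gain, double fb_tau, int n_cycles,
                    double tol) {
  const int n = ge.size();
  NumericVector y(n);
  double fb_avg = 0.0, gi = 0.0;
  bool converged = false;
  int cyc = 0;
  std::vector<double> gee(n);
  for (int i = 0; i < n; ++i) gee[i] = ge[i] * gbar_e;
  for (cyc = 1; cyc <= n_cycles; ++cyc) {
    double ymean = 0.0;
    for (int i = 0; i < n; ++i) ymean += y[i];
    ymean /= n;
    fb_avg += fb_tau * (ymean - fb_avg);
    gi = Gi * (ff + fb_gain * fb_avg);
    const double theta = a * gi + b;
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double excess = gee[i] - theta;
      double tgt = 0.0;
      if (excess > 0) {
        double gx = gamma * excess;
        tgt = gx / (1.0 + gx);
      }
      double ynew = y[i] + 0.5 * (tgt - y[i]);
      double d = std::fabs(ynew - y[i]);
      if (d > delta) delta = d;
      y[i] = ynew;
    }
    if (delta < tol) { converged = true; break; }
  }
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(y[i])) stop("settle_ge: non-finite activity");
  }
  return List::create(_["y"] = y, _["gi"] = gi,
                      _["cycles"] = std::min(cyc, n_cycles),
                      _["converged"] = converged);
}
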