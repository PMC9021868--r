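#include <Rcpp.h>
using namespace Rcpp;

// Two-step dynamic chill model, hourly recursion.
//
// An intermediate pool x relaxes toward a temperature-dependent equilibrium
// xs at first-order rate ak1; when the pool reaches `crit` at the end of an
// hour, a fraction xi (a logistic function of temperature) converts
// irreversibly to chill portions and is removed from the pool. Portions are
// never destroyed; only the intermediate pool is depletable by warm hours.
//
// The recursion is inherently sequential (state carried hour to hour), so it
// lives in C++; everything around it is vectorised R.
//
// Returns the per-hour converted amount (delta portions) and the final pool
// state, so a series can be processed in consecutive chunks with carried
// state.

// [[Rcpp::export]]
List dynamic_portions_cpp(NumericVector temp_c,
                          double slp, double tetmlt,
                          double e0, double e1,
                          double a0, double a1,
                          double crit, double kelvin_offset,
                          double x0) {
  const int n = temp_c.size();
  NumericVector delta(n);
  const double aa = a0 / a1;
  const double ee = e1 - e0;
  double x = x0;
  for (int i = 0; i < n; ++i) {
    const double tk  = temp_c[i] + kelvin_offset;
    const double xs  = aa * std::exp(ee / tk);
    const double ak1 = a1 * std::exp(-e1 / tk);
    const double inter_e = xs - (xs - x) * std::exp(-ak1);
    double d = 0.0;
    if (inter_e >= crit) {
      const double ftmprt = slp * tetmlt * (tk - tetmlt) / tk;
      const double sr = std::exp(ftmprt);
      const double xi = sr / (1.0 + sr);
      d = xi * inter_e;
    }
    x = inter_e - d;
    delta[i] = d;
  }
  return List::create(_["delta"] = delta, _["state"] = x);
}
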