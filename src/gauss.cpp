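// Exact sums over deposited metadynamics hills (value / s-derivative),
// with an optional per-query causal time cutoff. Hills farther than
// 8 sigma from the query contribute < 1e-14 of their height and are skipped.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_hill_sum")]]
NumericVector cpp_hill_sum(NumericVector center, NumericVector height,
                           NumericVector time, double sigma,
                           NumericVector s, NumericVector t_cutoff,
                           bool deriv) {
  const R_xlen_t nh = center.size(), nq = s.size();
  const bool per_query_cut = t_cutoff.size() == nq && nq > 1;
  const double cut = 8.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  NumericVector out(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    const double si = s[i];
    const double tc = per_query_cut ? t_cutoff[i] : t_cutoff[0];
    double acc = 0.0;
    for (R_xlen_t j = 0; j < nh; ++j) {
      if (time[j] > tc) break; // hills are time-ordered
      const double d = si - center[j];
      if (d > cut || d < -cut) continue;
      const double e = height[j] * std::exp(-d * d * inv2s2);
      acc += deriv ? (-d * invs2 * e) : e;
    }
    out[i] = acc;
  }
  return out;
}
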