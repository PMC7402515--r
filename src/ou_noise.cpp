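// Exact-update Ornstein-Uhlenbeck sampler.  Draws from the R RNG in the
// same order as the reference R implementation (stationary initial value
// first, then one innovation per sample), so results are identical for a
// given seed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".ou_noise_exact")]]
NumericVector ou_noise_exact(int n, double dt, double tau) {
  RNGScope rng;
  const double rho = std::exp(-dt / tau);
  const double sd = std::sqrt(1.0 - rho * rho);
  NumericVector out(n);
  double x = norm_rand();
  for (int k = 0; k < n; ++k) {
    x = rho * x + sd * norm_rand();
    out[k] = x;
  }
  return out;
}
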