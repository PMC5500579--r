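#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Counter-based generator: each variate is a pure function of (seed, counter),
// so trajectories are bit-reproducible and independent of R's global RNG state.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D4A2857FB5FC8FULL;
  return x ^ (x >> 31);
}

// uniform on (0,1), 53-bit resolution, never exactly 0 or 1
static inline double u01(uint64_t seed, uint64_t ctr) {
  uint64_t z = splitmix64(seed ^ (ctr * 0xD1B54A32D192ED03ULL + 0x8CB92BA72F3D8DD7ULL));
  return ((double)(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// standard normal via Box-Muller from two counter-based uniforms
static inline double znorm(uint64_t seed, uint64_t step) {
  double u1 = u01(seed, 2 * step);
  double u2 = u01(seed, 2 * step + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// Ito Euler-Maruyama for dx = -Q x dt + sqrt(2 (D0 + b x^2)) dW.
// The i-th stored sample is the state before the i-th update, so with
// burn_in = 0 the first returned value is x0.
// [[Rcpp::export]]
Rcpp::NumericVector em_simulate_cpp(double Q, double D0, double b,
                                    double n_d, double dt, double x0,
                                    double seed_d, double burn_in_d) {
  const R_xlen_t n = (R_xlen_t)n_d;
  const R_xlen_t burn = (R_xlen_t)burn_in_d;
  const uint64_t seed = (uint64_t)seed_d;
  Rcpp::NumericVector out(n);
  double x = x0;
  const R_xlen_t total = burn + n;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (i >= burn) out[i - burn] = x;
    if (i == total - 1) break;           // last stored sample needs no update
    const double d2 = D0 + b * x * x;
    x += -Q * x * dt + std::sqrt(2.0 * d2 * dt) * znorm(seed, (uint64_t)i);
    if (!std::isfinite(x))
      Rcpp::stop("non-finite state at step %g: diffusion blow-up (is Q > b?)",
                 (double)(i + 1));
  }
  return out;
}
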