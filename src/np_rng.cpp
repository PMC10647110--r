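// Mersenne-Twister stream compatible with the "classic" scientific-python
// RandomState so the two-moons fixture is reproduced bit-for-bit:
// 53-bit uniform doubles from consecutive 32-bit words, polar-method
// gaussians with a one-value cache, and masked-rejection bounded integers
// for Fisher-Yates shuffling.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

namespace {

struct LegacyRNG {
  std::mt19937 mt;
  bool has_gauss = false;
  double gauss = 0.0;

  explicit LegacyRNG(uint32_t seed) : mt(seed) {}

  uint32_t next_u32() { return mt(); }

  // (a >> 5) * 2^26 + (b >> 6), over 2^53
  double next_double() {
    uint32_t a = next_u32() >> 5, b = next_u32() >> 6;
    return (a * 67108864.0 + b) / 9007199254740992.0;
  }

  // polar (Marsaglia) method with cached second deviate
  double next_gauss() {
    if (has_gauss) {
      has_gauss = false;
      return gauss;
    }
    double f, x1, x2, r2;
    do {
      x1 = 2.0 * next_double() - 1.0;
      x2 = 2.0 * next_double() - 1.0;
      r2 = x1 * x1 + x2 * x2;
    } while (r2 >= 1.0 || r2 == 0.0);
    f = std::sqrt(-2.0 * std::log(r2) / r2);
    gauss = f * x1;
    has_gauss = true;
    return f * x2;
  }

  // uniform integer on [0, max] by masked rejection (max < 2^32)
  uint32_t next_interval(uint32_t max) {
    if (max == 0) return 0;
    uint32_t mask = max;
    mask |= mask >> 1;
    mask |= mask >> 2;
    mask |= mask >> 4;
    mask |= mask >> 8;
    mask |= mask >> 16;
    uint32_t value;
    while ((value = (next_u32() & mask)) > max)
      ;
    return value;
  }

  // in-place Fisher-Yates, highest index first
  void shuffle(Rcpp::IntegerVector x) {
    for (int i = x.size() - 1; i > 0; --i) {
      int j = static_cast<int>(next_interval(static_cast<uint32_t>(i)));
      int tmp = x[j];
      x[j] = x[i];
      x[i] = tmp;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_make_moons(int n_out, int n_in, double noise, int seed,
                          bool shuffle) {
  LegacyRNG rng(static_cast<uint32_t>(seed));
  int n = n_out + n_in;
  Rcpp::NumericMatrix X(n, 2);
  Rcpp::IntegerVector y(n);

  const double pi = 3.14159265358979323846;
  for (int i = 0; i < n_out; ++i) {
    double t = (n_out == 1) ? 0.0 : pi * i / (n_out - 1.0);
    X(i, 0) = std::cos(t);
    X(i, 1) = std::sin(t);
    y[i] = 0;
  }
  for (int i = 0; i < n_in; ++i) {
    double t = (n_in == 1) ? 0.0 : pi * i / (n_in - 1.0);
    X(n_out + i, 0) = 1.0 - std::cos(t);
    X(n_out + i, 1) = 1.0 - std::sin(t) - 0.5;
    y[n_out + i] = 1;
  }

  if (shuffle) {
    Rcpp::IntegerVector idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    rng.shuffle(idx);
    Rcpp::NumericMatrix Xs(n, 2);
    Rcpp::IntegerVector ys(n);
    for (int i = 0; i < n; ++i) {
      Xs(i, 0) = X(idx[i], 0);
      Xs(i, 1) = X(idx[i], 1);
      ys[i] = y[idx[i]];
    }
    X = Xs;
    y = ys;
  }

  if (noise > 0) {
    // row-major fill order, matching a C-ordered (n, 2) array
    for (int i = 0; i < n; ++i) {
      X(i, 0) += noise * rng.next_gauss();
      X(i, 1) += noise * rng.next_gauss();
    }
  }

  return Rcpp::List::create(Rcpp::Named("x") = X, Rcpp::Named("y") = y);
}

// raw pieces exposed for unit tests of the stream itself
// [[Rcpp::export]]
Rcpp::NumericVector cpp_legacy_uniform(int n, int seed) {
  LegacyRNG rng(static_cast<uint32_t>(seed));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.next_double();
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_legacy_normal(int n, int seed) {
  LegacyRNG rng(static_cast<uint32_t>(seed));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.next_gauss();
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_legacy_permutation(int n, int seed) {
  LegacyRNG rng(static_cast<uint32_t>(seed));
  Rcpp::IntegerVector idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  rng.shuffle(idx);
  return idx;
}
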