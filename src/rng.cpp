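// Counter-based pseudorandom number generation: Threefry-4x64 with 12 rounds.
// A stateless bijection (key, counter) -> 4 x 64 random bits; every variate in
// the package is addressed by a key tuple (seed, cell, mechanism, variable)
// and a counter, so that simulations are pure functions of the configuration
// and the global seed.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const uint64_t SKEIN_PARITY = 0x1BD11BDAA9FC1A22ULL;

// rotation constants for the 4x64 variant, two mixes per round, period 8
static const int ROT[8][2] = {
  {14, 16}, {52, 57}, {23, 40}, {5, 37},
  {25, 33}, {46, 12}, {58, 22}, {32, 32}
};

static inline uint64_t rotl64(uint64_t x, int n) {
  return (x << n) | (x >> (64 - n));
}

void threefry4x64_12(const uint64_t key[4], const uint64_t ctr[4],
                            uint64_t out[4]) {
  uint64_t ks[5];
  uint64_t x[4];
  ks[4] = SKEIN_PARITY;
  for (int i = 0; i < 4; ++i) {
    ks[i] = key[i];
    ks[4] ^= key[i];
    x[i] = ctr[i] + ks[i];
  }
  int inject = 0;
  for (int r = 0; r < 12; ++r) {
    if ((r & 1) == 0) {          // even round: mix (0,1) and (2,3)
      x[0] += x[1]; x[1] = rotl64(x[1], ROT[r % 8][0]); x[1] ^= x[0];
      x[2] += x[3]; x[3] = rotl64(x[3], ROT[r % 8][1]); x[3] ^= x[2];
    } else {                     // odd round: mix (0,3) and (2,1)
      x[0] += x[3]; x[3] = rotl64(x[3], ROT[r % 8][0]); x[3] ^= x[0];
      x[2] += x[1]; x[1] = rotl64(x[1], ROT[r % 8][1]); x[1] ^= x[2];
    }
    if ((r + 1) % 4 == 0) {
      ++inject;
      for (int i = 0; i < 4; ++i) x[i] += ks[(inject + i) % 5];
      x[3] += (uint64_t)inject;
    }
  }
  for (int i = 0; i < 4; ++i) out[i] = x[i];
}

double u64_to_unit(uint64_t v) {
  // take the top 53 bits -> double in [0, 1)
  return (double)(v >> 11) * (1.0 / 9007199254740992.0);
}

static inline void key_from_numeric(const double* k, uint64_t key[4]) {
  for (int i = 0; i < 4; ++i) key[i] = (uint64_t)k[i];
}

// Four uniforms in [0,1) for one (key, counter) pair.
// [[Rcpp::export(name = ".tf_uniforms")]]
NumericVector tf_uniforms(NumericVector key, double counter) {
  if (key.size() != 4) stop("key must have 4 components");
  uint64_t k[4], c[4] = {(uint64_t)counter, 0u, 0u, 0u}, o[4];
  key_from_numeric(REAL(key), k);
  threefry4x64_12(k, c, o);
  NumericVector out(4);
  for (int i = 0; i < 4; ++i) out[i] = u64_to_unit(o[i]);
  return out;
}

// Batched uniforms: one row of 4 uniforms per (key row, counter element).
// [[Rcpp::export(name = ".tf_uniforms_batch")]]
NumericMatrix tf_uniforms_batch(NumericMatrix keys, NumericVector counters) {
  int n = keys.nrow();
  if (keys.ncol() != 4) stop("keys must have 4 columns");
  if (counters.size() != n && counters.size() != 1)
    stop("counters must have length 1 or nrow(keys)");
  NumericMatrix out(n, 4);
  uint64_t k[4], c[4] = {0u, 0u, 0u, 0u}, o[4];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 4; ++j) k[j] = (uint64_t)keys(i, j);
    c[0] = (uint64_t)(counters.size() == 1 ? counters[0] : counters[i]);
    threefry4x64_12(k, c, o);
    for (int j = 0; j < 4; ++j) out(i, j) = u64_to_unit(o[j]);
  }
  return out;
}

// Standard-normal pairs via Box-Muller from the first two uniforms of each
// block; both outputs of every transform are returned (no rejection).
// [[Rcpp::export(name = ".tf_normals_batch")]]
NumericMatrix tf_normals_batch(NumericMatrix keys, NumericVector counters) {
  int n = keys.nrow();
  if (keys.ncol() != 4) stop("keys must have 4 columns");
  NumericMatrix out(n, 4);
  uint64_t k[4], c[4] = {0u, 0u, 0u, 0u}, o[4];
  const double TWO_PI = 6.283185307179586476925286766559;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 4; ++j) k[j] = (uint64_t)keys(i, j);
    c[0] = (uint64_t)(counters.size() == 1 ? counters[0] : counters[i]);
    threefry4x64_12(k, c, o);
    double u[4];
    for (int j = 0; j < 4; ++j) u[j] = u64_to_unit(o[j]);
    for (int p = 0; p < 2; ++p) {
      double u1 = 1.0 - u[2 * p];   // in (0, 1]: excludes log(0)
      double u2 = u[2 * p + 1];
      double r = std::sqrt(-2.0 * std::log(u1));
      out(i, 2 * p)     = r * std::cos(TWO_PI * u2);
      out(i, 2 * p + 1) = r * std::sin(TWO_PI * u2);
    }
  }
  return out;
}
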