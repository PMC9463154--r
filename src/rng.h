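#ifndef BIOKG_RNG_H
#define BIOKG_RNG_H

#include <cstdint>

// Deterministic 64-bit RNG (splitmix64-seeded xorshift128+), independent of
// R's RNG so that walk generation and skip-gram training are bit-reproducible
// for a given seed regardless of the caller's RNG state.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    // splitmix64 to spread the seed
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9e3779b97f4a7c15ULL);
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  inline uint64_t bounded(uint64_t n) { return next() % n; }
};

#endif
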