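#ifndef SUPERCOILR_RNG_H
#define SUPERCOILR_RNG_H

#include <Rmath.h>
#include <cstdint>
#include <cmath>

// Fast internal RNG for the simulation kernels: xoshiro256++ uniforms with
// cached Box-Muller normals.  The state is seeded from R's RNG stream, so
// runs remain bitwise reproducible under set.seed() while avoiding the
// per-draw cost of R's inversion sampler in the inner loops.

namespace scr {

struct FastRng {
  uint64_t s[4];
  bool have_cached = false;
  double cached = 0.0;

  // seed from R's RNG (caller must hold the RNG state, e.g. via RNGScope)
  void seed_from_r() {
    uint64_t sm = 0;
    for (int k = 0; k < 4; ++k) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      sm ^= (hi << 32) | lo;
      // splitmix64 scramble so nearby R seeds give unrelated states
      sm += 0x9e3779b97f4a7c15ULL;
      uint64_t z = sm;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[k] = z ^ (z >> 31);
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x853c49e6748fea9bULL;
    have_cached = false;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {            // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double norm() {            // standard normal (Box-Muller, cached)
    if (have_cached) {
      have_cached = false;
      return cached;
    }
    double u1 = 1.0 - unif();       // (0, 1]
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

}  // namespace scr

#endif
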