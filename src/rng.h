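#ifndef ENTROPULL_RNG_H
#define ENTROPULL_RNG_H

#include <cstdint>
#include <cmath>

// splitmix64-seeded xoshiro256+ with explicit bit-level uniform/gaussian
// draws, so traces are reproducible independently of the C++ standard
// library's distribution implementations.
struct Rng {
  uint64_t s[4];

  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform in (0, 1] (safe for log)
  inline double unif_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }

  // standard normal (Box-Muller, no caching so the stream is stateless)
  inline double gauss() {
    double u1 = unif_pos();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }

  // uniform integer in [0, n)
  inline int below(int n) { return (int)(unif() * n); }

  // random unit vector
  inline void unit_vec(double v[3]) {
    double n2;
    do {
      v[0] = 2.0 * unif() - 1.0;
      v[1] = 2.0 * unif() - 1.0;
      v[2] = 2.0 * unif() - 1.0;
      n2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    } while (n2 > 1.0 || n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    v[0] *= inv; v[1] *= inv; v[2] *= inv;
  }
};

#endif
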