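#ifndef HYBRIDCME_RNG_H
#define HYBRIDCME_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded PRNG (splitmix64-seeded xoshiro256++).
// Realization i of an ensemble with root seed s uses the child stream
// obtained by seeding splitmix64 with s ^ (golden-ratio constant * (i+1));
// streams are therefore reproducible and independent of execution order.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    // avoid the all-zero state (probability ~2^-256 anyway)
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform on (0, 1]
  double unif_pos() { return 1.0 - unif(); }
  // uniform on (0, 1)
  double unif_open() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
};

#endif
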