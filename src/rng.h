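#ifndef RWEXPLORE_RNG_H
#define RWEXPLORE_RNG_H

#include <cstdint>

// Counter-based seeding: a single user seed plus a stream index (one stream
// per realization) gives independent, bit-reproducible substreams regardless
// of execution order. splitmix64 scrambles (seed, stream) into the xoshiro
// state; xoshiro256++ supplies the draws.
static inline uint64_t rw_splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RWRng {
  uint64_t s[4];
  RWRng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD2B74407B1CE6E93ULL + 0x8CB92BA72F3D8DD7ULL);
    s[0] = rw_splitmix64(x);
    s[1] = rw_splitmix64(x);
    s[2] = rw_splitmix64(x);
    s[3] = rw_splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
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
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in {0, ..., n-1}; n small so modulo-free scaling is fine
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

#endif
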