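// Minimal fast RNG for the simulation engine: xoshiro256++ uniforms,
// splitmix64 seeding, and a Marsaglia-Tsang ziggurat normal sampler.
// Self-contained so streams are identical across standard libraries.
#ifndef PFCWM_RNG_H
#define PFCWM_RNG_H

#include <cstdint>
#include <cmath>

namespace pfcwm {

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }
  // uniform on (0, 1]
  inline double unif_pos() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
};

// Ziggurat normal sampler (Marsaglia & Tsang 2000, 128 layers), double
// precision tables shared per process.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31: |hz| is a signed 32-bit draw
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double draw(Xoshiro256 &rng) const {
    for (;;) {
      const uint64_t u = rng.next();
      const int32_t hz = (int32_t)(u & 0xffffffffu);
      const uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // fix-up
      const double r = 3.442619855899;
      if (iz == 0) {
        double xx, yy;
        do {
          xx = -std::log(rng.unif_pos()) / r;
          yy = -std::log(rng.unif_pos());
        } while (yy + yy < xx * xx);
        return hz > 0 ? r + xx : -(r + xx);
      }
      const double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      // else retry with a fresh draw
    }
  }
};

inline const Ziggurat &ziggurat() {
  static const Ziggurat z;
  return z;
}

} // namespace pfcwm
#endif
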