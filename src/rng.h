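#ifndef MFESIM_RNG_H
#define MFESIM_RNG_H

#include <cstdint>
#include <cmath>

// Small counter-independent RNG streams (splitmix64-seeded xoshiro256++),
// so every neuron / subsystem gets its own reproducible stream derived from
// one master seed, independent of event interleaving.

struct SplitMix64 {
    uint64_t x;
    explicit SplitMix64(uint64_t s) : x(s) {}
    uint64_t next() {
        uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
};

struct Xoshiro256pp {
    uint64_t s[4];
    Xoshiro256pp() { init(0x9E3779B97F4A7C15ULL); }
    void init(uint64_t seed) {
        SplitMix64 sm(seed);
        for (int i = 0; i < 4; ++i) s[i] = sm.next();
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    uint64_t next() {
        const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return r;
    }
    // uniform in [0, 1)
    double unif() { return (next() >> 11) * 0x1.0p-53; }
    // exponential with given rate (per unit time)
    double expo(double rate) {
        double u = unif();
        while (u <= 0.0) u = unif();
        return -std::log(u) / rate;
    }
};

inline uint64_t stream_seed(uint64_t master, uint64_t stream) {
    SplitMix64 sm(master ^ (0xD1B54A32D192ED03ULL * (stream + 1)));
    return sm.next();
}

#endif
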