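#ifndef CHLOROSMITH_KMER_ENCODE_H
#define CHLOROSMITH_KMER_ENCODE_H

#include <string>
#include <cstdint>
#include <cstddef>

// 2-bit k-mer encoding (A=0, C=1, G=2, T=3), k <= 63 in an unsigned
// __int128. The integer order matches lexicographic order on ACGT, so
// canonical-by-min is identical to string canonicalization.
typedef unsigned __int128 u128;

struct U128Hash {
    size_t operator()(u128 x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        lo ^= hi * 0x9E3779B97F4A7C15ULL;
        lo ^= lo >> 33; lo *= 0xFF51AFD7ED558CCDULL; lo ^= lo >> 33;
        return (size_t)lo;
    }
};

static inline int enc_base(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
    }
}

static const char KMER_DEC[4] = {'A', 'C', 'G', 'T'};

static inline u128 kmer_mask(int k) {
    return (((u128)1) << (2 * k)) - 1;
}

static inline u128 rc_kmer(u128 x, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (u128)(3u - (unsigned)(x & 3));
        x >>= 2;
    }
    return r;
}

static inline std::string decode_kmer(u128 x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = KMER_DEC[(unsigned)(x & 3)];
        x >>= 2;
    }
    return s;
}

static inline u128 encode_kmer(const std::string& s) {
    u128 x = 0;
    for (char c : s) x = (x << 2) | (u128)enc_base(c);
    return x;
}

// call f(canonical_kmer) for every valid (ACGT-only) k-mer of s
template <typename F>
static inline void for_each_canon(const std::string& s, int k, F f) {
    u128 mask = kmer_mask(k);
    u128 fwd = 0, rev = 0;
    int run = 0;
    const int shift = 2 * (k - 1);
    for (size_t i = 0; i < s.size(); ++i) {
        int b = enc_base(s[i]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (u128)(unsigned)b) & mask;
        rev = (rev >> 2) | ((u128)(3u - (unsigned)b) << shift);
        if (++run >= k) f(fwd < rev ? fwd : rev);
    }
}

#endif
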