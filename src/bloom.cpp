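#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Seeded 64-bit FNV-1a over the exact bytes of the string, finalized with
// splitmix64.  Two derived hashes drive a Kirsch-Mitzenmacher double-hashing
// scheme: bit i = (h1 + i*h2) mod m, i in [0, k).  h2 is forced odd so the
// probe sequence cycles through all residues when m is even.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a64(const char *s, R_xlen_t len, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ splitmix64(seed);
  for (R_xlen_t i = 0; i < len; ++i) {
    h ^= (uint64_t)(uint8_t)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline void hash_pair(SEXP str, uint64_t seed, uint64_t *h1, uint64_t *h2) {
  const char *s = CHAR(str);
  R_xlen_t len = LENGTH(str);
  uint64_t h = fnv1a64(s, len, seed);
  *h1 = splitmix64(h);
  *h2 = splitmix64(h ^ 0xA5A5A5A5A5A5A5A5ULL) | 1ULL;
}

// [[Rcpp::export(name = ".bloom_insert")]]
RawVector bloom_insert(RawVector bits, double m_, int k, double seed_,
                       CharacterVector values) {
  uint64_t m = (uint64_t)m_;
  uint64_t seed = (uint64_t)seed_;
  RawVector out = clone(bits);
  for (R_xlen_t j = 0; j < values.size(); ++j) {
    SEXP str = STRING_ELT(values, j);
    if (str == NA_STRING) stop("NA values cannot be inserted");
    uint64_t h1, h2;
    hash_pair(str, seed, &h1, &h2);
    for (int i = 0; i < k; ++i) {
      uint64_t pos = (h1 + (uint64_t)i * h2) % m;
      out[pos >> 3] |= (Rbyte)(1u << (pos & 7u));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bloom_query")]]
LogicalVector bloom_query(RawVector bits, double m_, int k, double seed_,
                          CharacterVector values) {
  uint64_t m = (uint64_t)m_;
  uint64_t seed = (uint64_t)seed_;
  R_xlen_t n = values.size();
  LogicalVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    SEXP str = STRING_ELT(values, j);
    if (str == NA_STRING) { out[j] = NA_LOGICAL; continue; }
    uint64_t h1, h2;
    hash_pair(str, seed, &h1, &h2);
    bool hit = true;
    for (int i = 0; i < k; ++i) {
      uint64_t pos = (h1 + (uint64_t)i * h2) % m;
      if (!(bits[pos >> 3] & (1u << (pos & 7u)))) { hit = false; break; }
    }
    out[j] = hit;
  }
  return out;
}
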