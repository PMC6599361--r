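#include <Rcpp.h>
#include <cstdint>
#include <string>

// Fixed-constant 64-bit mixing hash used for all fingerprint identifiers.
// Identifiers must be byte-identical across platforms and R sessions, so the
// constants are written into the code and no library hash is used.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a64(const char *s) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    h ^= (uint64_t)(*p);
    h *= 0x100000001B3ULL;
  }
  return h;
}

static std::string hex64(uint64_t v) {
  static const char *digits = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) {
    out[i] = digits[v & 0xF];
    v >>= 4;
  }
  return out;
}

static uint64_t chain_hash(const Rcpp::CharacterVector &tokens) {
  uint64_t h = 0x8A5CD789635D2DFFULL; // fixed chain seed
  for (R_xlen_t i = 0; i < tokens.size(); ++i) {
    h = splitmix64(h ^ fnv1a64(Rcpp::as<const char *>(tokens[i])));
  }
  return h;
}

// [[Rcpp::export(name = ".cs_hash_tokens")]]
std::string cs_hash_tokens(Rcpp::CharacterVector tokens) {
  return hex64(chain_hash(tokens));
}

// [[Rcpp::export(name = ".cs_hash_token_list")]]
Rcpp::CharacterVector cs_hash_token_list(Rcpp::List token_lists) {
  R_xlen_t n = token_lists.size();
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcpp::CharacterVector toks(token_lists[i]);
    out[i] = hex64(chain_hash(toks));
  }
  return out;
}
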