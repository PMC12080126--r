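// Deterministic string hash used by the mock docking scorer and the
// fingerprint folder: 64-bit FNV-1a with a murmur-style avalanche
// finalizer (so keys differing in a single trailing character still map
// to independent values), reduced modulo a prime.  Plain unsigned
// integer arithmetic, so results are identical across platforms and
// runs.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::NumericVector hash_strings_cpp(Rcpp::CharacterVector x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) {
    const char* s = CHAR(STRING_ELT(x, k));
    uint64_t h = 1469598103934665603ULL;           // FNV-1a 64 offset
    for (const char* p = s; *p; ++p) {
      h ^= static_cast<unsigned char>(*p);
      h *= 1099511628211ULL;                       // FNV-1a 64 prime
    }
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;      // avalanche
    h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
    h ^= h >> 33;
    out[k] = static_cast<double>(h % 1000000007ULL);
  }
  return out;
}
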