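#include <Rcpp.h>
using namespace Rcpp;

// 32-bit FNV-1a over UTF-8 bytes; returned as double because R has no uint32.
// The offset basis and prime are the published constants; hash_version "fnv1a-32".
static uint32_t fnv1a32(const char* s) {
  uint32_t h = 2166136261u;
  for (const unsigned char* p = (const unsigned char*)s; *p; ++p) {
    h ^= (uint32_t)(*p);
    h *= 16777619u;
  }
  return h;
}

// [[Rcpp::export(name = ".fnv1a32")]]
NumericVector fnv1a32_vec(CharacterVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    out[i] = (double)fnv1a32(CHAR(STRING_ELT(x, i)));
  }
  return out;
}
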