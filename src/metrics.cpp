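#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Decode UTF-8 bytes to code points; offsets and match windows are counted in
// code points so results agree with R's character semantics.
static std::vector<uint32_t> decode_utf8(const char *s) {
  std::vector<uint32_t> out;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(s);
  while (*p) {
    uint32_t cp;
    int n;
    if (*p < 0x80)      { cp = *p; n = 1; }
    else if (*p < 0xE0) { cp = *p & 0x1F; n = 2; }
    else if (*p < 0xF0) { cp = *p & 0x0F; n = 3; }
    else                { cp = *p & 0x07; n = 4; }
    ++p;
    for (int i = 1; i < n && *p; ++i, ++p) cp = (cp << 6) | (*p & 0x3F);
    out.push_back(cp);
  }
  return out;
}

static double jaro_cp(const std::vector<uint32_t> &a, const std::vector<uint32_t> &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return 0.0;
  const int win = std::max(0, std::max(la, lb) / 2 - 1);
  std::vector<char> amatch(la, 0), bmatch(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - win), hi = std::min(lb - 1, i + win);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = bmatch[j] = 1;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  // transpositions: matched characters out of order, counted pairwise
  int t2 = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!amatch[i]) continue;
    while (!bmatch[j]) ++j;
    if (a[i] != b[j]) ++t2;
    ++j;
  }
  const double tau = t2 / 2.0;
  return ((double)m / la + (double)m / lb + (m - tau) / m) / 3.0;
}

static double jw_cp(const std::vector<uint32_t> &a, const std::vector<uint32_t> &b,
                    double p, int max_prefix) {
  const double j = jaro_cp(a, b);
  int l = 0;
  const int lim = std::min((int)std::min(a.size(), b.size()), max_prefix);
  while (l < lim && a[l] == b[l]) ++l;
  return j + l * p * (1.0 - j);
}

// [[Rcpp::export(name = ".jaro_pairs")]]
NumericVector jaro_pairs(CharacterVector s, CharacterVector t) {
  const R_xlen_t n = std::max(s.size(), t.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::vector<uint32_t> a = decode_utf8(Rf_translateCharUTF8(s[i % s.size()]));
    std::vector<uint32_t> b = decode_utf8(Rf_translateCharUTF8(t[i % t.size()]));
    out[i] = jaro_cp(a, b);
  }
  return out;
}

// [[Rcpp::export(name = ".jw_pairs")]]
NumericVector jw_pairs(CharacterVector s, CharacterVector t, double p, int max_prefix) {
  const R_xlen_t n = std::max(s.size(), t.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::vector<uint32_t> a = decode_utf8(Rf_translateCharUTF8(s[i % s.size()]));
    std::vector<uint32_t> b = decode_utf8(Rf_translateCharUTF8(t[i % t.size()]));
    out[i] = jw_cp(a, b, p, max_prefix);
  }
  return out;
}

// All-pairs Jaro-Winkler between two token vectors; rows follow s, columns t.
// [[Rcpp::export(name = ".jw_cross")]]
NumericMatrix jw_cross(CharacterVector s, CharacterVector t, double p, int max_prefix) {
  const R_xlen_t ns = s.size(), nt = t.size();
  std::vector<std::vector<uint32_t>> as(ns), bs(nt);
  for (R_xlen_t i = 0; i < ns; ++i) as[i] = decode_utf8(Rf_translateCharUTF8(s[i]));
  for (R_xlen_t j = 0; j < nt; ++j) bs[j] = decode_utf8(Rf_translateCharUTF8(t[j]));
  NumericMatrix out(ns, nt);
  for (R_xlen_t i = 0; i < ns; ++i)
    for (R_xlen_t j = 0; j < nt; ++j)
      out(i, j) = jw_cp(as[i], bs[j], p, max_prefix);
  return out;
}
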