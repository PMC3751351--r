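#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
#include <string>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3 (so numeric order == lexicographic order
// of the decoded string, and the canonical form is the numeric minimum of the
// forward and reverse-complement codes). Any other byte breaks the window.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

typedef std::unordered_map<uint64_t, int> kmer_map;

// Slide a k-window over one sequence, feeding the canonical code of every
// all-ACGT window to the map. Rolling update keeps this O(len).
static void count_sequence(const char* s, R_xlen_t len, int k, kmer_map& m) {
  const uint64_t mask = (2 * k == 64) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  for (R_xlen_t i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (filled < k) ++filled;
    if (filled == k) ++m[fwd < rc ? fwd : rc];
  }
}

static kmer_map count_all(const CharacterVector& seqs, int k) {
  if (k < 1 || k > 31)
    stop("k must be between 1 and 31");
  kmer_map m;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    if (el == NA_STRING) continue;
    count_sequence(CHAR(el), LENGTH(el), k, m);
  }
  return m;
}

static std::string decode(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string out(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_kmer_counts")]]
IntegerVector cpp_kmer_counts(CharacterVector seqs, int k) {
  kmer_map m = count_all(seqs, k);
  // emit in sorted (canonical-lexicographic) key order for reproducibility
  std::map<uint64_t, int> sorted(m.begin(), m.end());
  IntegerVector counts(sorted.size());
  CharacterVector names(sorted.size());
  R_xlen_t i = 0;
  for (std::map<uint64_t, int>::const_iterator it = sorted.begin();
       it != sorted.end(); ++it, ++i) {
    counts[i] = it->second;
    names[i] = decode(it->first, k);
  }
  counts.attr("names") = names;
  return counts;
}

// Histogram of counts-of-counts without materialising k-mer strings; this is
// the memory-friendly path for read sets.
// [[Rcpp::export(name = ".cpp_kmer_spectrum")]]
DataFrame cpp_kmer_spectrum(CharacterVector seqs, int k) {
  kmer_map m = count_all(seqs, k);
  std::map<int, double> hist;
  for (kmer_map::const_iterator it = m.begin(); it != m.end(); ++it)
    hist[it->second] += 1.0;
  IntegerVector x(hist.size());
  NumericVector z(hist.size());
  R_xlen_t i = 0;
  for (std::map<int, double>::const_iterator it = hist.begin();
       it != hist.end(); ++it, ++i) {
    x[i] = it->first;
    z[i] = it->second;
  }
  return DataFrame::create(Named("abundance") = x, Named("count") = z);
}
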