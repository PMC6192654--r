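#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 2-bit nucleotide code; anything outside upper-case ACGT is "missing" and
// invalidates every window it touches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Full k-mer spectrum of a set of sequences: counts of every k-mer observed in
// 1-bp sliding windows, skipping windows that contain a non-ACGT character.
// Returns counts (named, sorted lexicographically) and the total number of
// valid windows.
// [[Rcpp::export]]
List kmer_spectrum_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be an integer in [1, 31]");
  std::unordered_map<uint64_t, double> counts;
  double total = 0.0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) stop("sequences must not be NA");
    const char *p = CHAR(STRING_ELT(seqs, s));
    const int L = LENGTH(STRING_ELT(seqs, s));
    if (L < k) continue;
    uint64_t code = 0;
    int run = 0;  // consecutive valid bases ending at current position
    for (int i = 0; i < L; ++i) {
      const int b = base_code(p[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) { counts[code] += 1.0; total += 1.0; }
    }
  }
  std::vector<std::pair<uint64_t, double> > v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  NumericVector ct(v.size());
  CharacterVector nm(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    nm[i] = decode_kmer(v[i].first, k);
    ct[i] = v[i].second;
  }
  ct.attr("names") = nm;
  return List::create(_["counts"] = ct, _["total"] = total);
}

// Occurrence counts of a fixed set of ACGT patterns in each sequence
// (overlapping occurrences all counted), plus the number of valid (N-free)
// windows per sequence for every distinct pattern length. Used for per-region
// relative frequencies and truth-table bookkeeping.
// [[Rcpp::export]]
List pattern_counts_cpp(CharacterVector seqs, CharacterVector patterns) {
  const int np = patterns.size();
  const int ns = seqs.size();
  std::map<int, std::unordered_map<uint64_t, std::vector<int> > > maps;
  for (int j = 0; j < np; ++j) {
    if (patterns[j] == NA_STRING) stop("patterns must not be NA");
    const char *q = CHAR(STRING_ELT(patterns, j));
    const int k = LENGTH(STRING_ELT(patterns, j));
    if (k < 1 || k > 31) stop("pattern length must be in [1, 31]");
    uint64_t code = 0;
    for (int i = 0; i < k; ++i) {
      const int b = base_code(q[i]);
      if (b < 0) stop("patterns must contain only A, C, G, T");
      code = (code << 2) | (uint64_t)b;
    }
    maps[k][code].push_back(j);
  }
  std::vector<int> kd;
  for (std::map<int, std::unordered_map<uint64_t, std::vector<int> > >::iterator
         it = maps.begin(); it != maps.end(); ++it)
    kd.push_back(it->first);
  IntegerMatrix counts(ns, np);
  NumericMatrix valid(ns, (int)kd.size());
  for (int s = 0; s < ns; ++s) {
    if (seqs[s] == NA_STRING) stop("sequences must not be NA");
    const char *p = CHAR(STRING_ELT(seqs, s));
    const int L = LENGTH(STRING_ELT(seqs, s));
    for (size_t ki = 0; ki < kd.size(); ++ki) {
      const int k = kd[ki];
      if (L < k) continue;
      const std::unordered_map<uint64_t, std::vector<int> > &m = maps[k];
      const uint64_t mask = (1ULL << (2 * k)) - 1;
      uint64_t code = 0;
      int run = 0;
      double nv = 0.0;
      for (int i = 0; i < L; ++i) {
        const int b = base_code(p[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          nv += 1.0;
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator hit =
            m.find(code);
          if (hit != m.end())
            for (size_t j = 0; j < hit->second.size(); ++j)
              counts(s, hit->second[j]) += 1;
        }
      }
      valid(s, ki) = nv;
    }
  }
  return List::create(_["counts"] = counts,
                      _["valid_windows"] = valid,
                      _["k"] = IntegerVector(kd.begin(), kd.end()));
}
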