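#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Enumerate canonical k-mer codes of one sequence into `out` (appends).
// Windows containing any non-ACGT character are skipped.
static void seq_canonical_codes(const char *s, R_xlen_t n, int k,
                                std::vector<uint64_t> &out) {
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 2 || k > 26)
    stop("k must be between 2 and 26");
  std::unordered_map<uint64_t, double> tab;
  std::vector<uint64_t> codes;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char *s = CHAR(STRING_ELT(seqs, j));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, j));
    codes.clear();
    seq_canonical_codes(s, n, k, codes);
    if (tab.bucket_count() < codes.size()) tab.reserve(codes.size());
    for (uint64_t code : codes) tab[code] += 1.0;
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector code_out(keys.size()), count_out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    code_out[i] = (double)keys[i];
    count_out[i] = tab[keys[i]];
  }
  return List::create(_["code"] = code_out, _["count"] = count_out);
}

// Distinct canonical k-mer codes of a single sequence, sorted.
// [[Rcpp::export]]
NumericVector seq_kmer_codes_cpp(CharacterVector seq, int k) {
  if (seq.size() != 1) stop("seq must be a single string");
  if (k < 2 || k > 26) stop("k must be between 2 and 26");
  std::vector<uint64_t> codes;
  seq_canonical_codes(CHAR(STRING_ELT(seq, 0)), LENGTH(STRING_ELT(seq, 0)), k,
                      codes);
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  NumericVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = (double)codes[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector kmer_decode_cpp(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = CODE_BASE[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_encode_cpp(CharacterVector kmers, bool canonical) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    int k = LENGTH(STRING_ELT(kmers, i));
    if (k < 2 || k > 26) stop("k-mer length must be between 2 and 26");
    uint64_t fwd = 0, rev = 0;
    const int shift = 2 * (k - 1);
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) stop("non-ACGT character in k-mer '%s'", s);
      fwd = (fwd << 2) | (uint64_t)c;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    }
    out[i] = (double)(canonical && rev < fwd ? rev : fwd);
  }
  return out;
}
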