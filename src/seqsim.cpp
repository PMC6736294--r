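#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': return 'N'; case 'n': return 'n';
  default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
    buf.resize(n);
    for (R_xlen_t j = 0; j < n; ++j) buf[j] = comp_base(s[n - 1 - j]);
    out[i] = buf;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// Apply iid per-base substitution errors at rate `error_rate`, using R's RNG
// (deterministic under set.seed). Substituted base is uniform over the other 3.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double error_rate) {
  if (error_rate <= 0) return seqs;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
    int nerr = (int)R::rbinom((double)n, error_rate);
    if (nerr == 0) { out[i] = STRING_ELT(seqs, i); continue; }
    buf.assign(s, n);
    for (int e = 0; e < nerr; ++e) {
      R_xlen_t pos = (R_xlen_t)(R::unif_rand() * n);
      if (pos >= n) pos = n - 1;
      char cur = buf[pos];
      char sub = BASES[(int)(R::unif_rand() * 4) & 3];
      while (sub == cur) sub = BASES[(int)(R::unif_rand() * 4) & 3];
      buf[pos] = sub;
    }
    out[i] = buf;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
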