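#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[s.size() - 1 - j] = comp_base(s[j]);
    out[i] = r;
  }
  return out;
}

// iid per-base substitution errors at rate `rate`, via geometric skipping so
// the cost is proportional to the number of errors, not the number of bases.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector add_errors_cpp(CharacterVector seqs, double rate) {
  R_xlen_t n = seqs.size();
  if (rate <= 0.0) return clone(seqs);
  CharacterVector out(n);
  const char* bases = "ACGT";
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    double skip = R::rgeom(rate);
    R_xlen_t pos = (R_xlen_t) skip;
    while (pos >= 0 && pos < (R_xlen_t) s.size()) {
      char cur = s[pos];
      if (cur == 'A' || cur == 'C' || cur == 'G' || cur == 'T') {
        int k = (int) (unif_rand() * 3.0);
        if (k > 2) k = 2;
        // pick among the three other bases
        int idx = 0;
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == cur) continue;
          if (idx == k) { s[pos] = bases[b]; break; }
          ++idx;
        }
      }
      pos += 1 + (R_xlen_t) R::rgeom(rate);
    }
    out[i] = s;
  }
  return out;
}

// Hamming distance between equal-length strings; NA_INTEGER if lengths differ.
// [[Rcpp::export]]
int str_mismatches_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) return NA_INTEGER;
  int mm = 0;
  for (size_t j = 0; j < a.size(); ++j)
    if (a[j] != b[j]) ++mm;
  return mm;
}
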