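// Reverse complement over the IUPAC DNA alphabet.

#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    case 'N': return 'N'; case 'n': return 'n';
    default: return 0;
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), ' ');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = comp(s[s.size() - 1 - j]);
      if (c == 0) stop("non-IUPAC character in DNA string");
      r[j] = c;
    }
    out[i] = r;
  }
  return out;
}
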