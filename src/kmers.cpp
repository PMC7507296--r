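#include <Rcpp.h>
#include <map>
#include <string>
using namespace Rcpp;

static inline char norm_base(char c) {
  switch (c) {
  case 'a': return 'A';
  case 'c': return 'C';
  case 'g': return 'G';
  case 't': return 'T';
  case 'A': case 'C': case 'G': case 'T': return c;
  default: return 0; // anything else (N, IUPAC codes, gaps) invalidates a window
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return 'A'; // 'T'
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Count every length-k window made solely of A/C/G/T (case-insensitive);
// windows containing any other character are skipped. With canonical = true
// a window and its reverse complement are pooled under the lexicographically
// smaller of the two strings. Keys come back sorted (std::map) so the result
// is deterministic.
// [[Rcpp::export]]
NumericVector cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  std::map<std::string, double> tab;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (CharacterVector::is_na(seqs[s])) continue;
    std::string seq = as<std::string>(seqs[s]);
    const R_xlen_t n = (R_xlen_t) seq.size();
    for (R_xlen_t i = 0; i < n; ++i) seq[i] = norm_base(seq[i]);
    R_xlen_t run = 0; // length of current valid A/C/G/T run ending at i
    for (R_xlen_t i = 0; i < n; ++i) {
      run = seq[i] ? run + 1 : 0;
      if (run >= k) {
        std::string kmer = seq.substr(i - k + 1, k);
        if (canonical) {
          std::string rc = revcomp(kmer);
          if (rc < kmer) kmer = rc;
        }
        tab[kmer] += 1.0;
      }
    }
  }
  NumericVector out(tab.size());
  CharacterVector keys(tab.size());
  R_xlen_t i = 0;
  for (std::map<std::string, double>::const_iterator it = tab.begin();
       it != tab.end(); ++it, ++i) {
    keys[i] = it->first;
    out[i] = it->second;
  }
  out.names() = keys;
  return out;
}
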