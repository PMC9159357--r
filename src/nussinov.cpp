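#include <Rcpp.h>
#include <vector>
#include <cctype>

// Maximum base-pairing (Nussinov) dynamic program with a minimum loop
// length, scored -1 per GC/AU/GU pair: a surrogate pseudo-energy, not a
// thermodynamic free energy.

static inline bool can_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
Rcpp::NumericVector nussinov_score(Rcpp::CharacterVector sequences,
                                   int min_loop = 3) {
  int m = sequences.size();
  Rcpp::NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    std::string seq = Rcpp::as<std::string>(sequences[s]);
    int n = seq.size();
    if (n == 0) { out[s] = 0.0; continue; }
    for (int i = 0; i < n; ++i) seq[i] = std::toupper(seq[i]);
    std::vector<int> dp((size_t)n * n, 0);
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int best = dp[(size_t)i * n + j - 1];
        for (int k = i; k + min_loop < j; ++k) {
          if (can_pair(seq[k], seq[j])) {
            int left = (k > i) ? dp[(size_t)i * n + k - 1] : 0;
            int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + j - 1] : 0;
            int cand = left + 1 + inner;
            if (cand > best) best = cand;
          }
        }
        dp[(size_t)i * n + j] = best;
      }
    }
    out[s] = -(double)dp[(size_t)0 * n + n - 1];
  }
  return out;
}
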