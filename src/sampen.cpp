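#include <Rcpp.h>
using namespace Rcpp;

// Count m- and (m+1)-length template matches under the Chebyshev (maximum)
// distance, within segments only: templates never span a segment boundary,
// and self-matches are excluded. Both templates of a pair may come from
// different segments (the discontinuous-segment estimator pools them).
//
// x        : concatenated samples
// seg_ends : cumulative segment lengths (1-based end index of each segment)
// m        : template length
// r        : absolute tolerance
// [[Rcpp::export]]
List count_matches(NumericVector x, IntegerVector seg_ends, int m, double r) {
  int n_seg = seg_ends.size();
  // collect valid template start indices: within a segment, room for m+1
  // (the Richman-Moorman convention: both the m- and (m+1)-counts run over
  // the extendable templates, so A/B is a conditional probability)
  std::vector<int> starts_m1;
  int beg = 0;
  for (int s = 0; s < n_seg; ++s) {
    int end = seg_ends[s]; // exclusive, 0-based
    for (int i = beg; i + m + 1 <= end; ++i) starts_m1.push_back(i);
    beg = end;
  }
  // B: matches of length m among templates that can be EXTENDED (the
  // conditional-probability convention: count pairs over the same template
  // set for m and m+1, so the ratio is a true conditional probability)
  long long A = 0, B = 0;
  int nt = starts_m1.size();
  for (int i = 0; i < nt; ++i) {
    int a = starts_m1[i];
    for (int j = i + 1; j < nt; ++j) {
      int b = starts_m1[j];
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[a + k] - x[b + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[a + m] - x[b + m]) <= r) ++A;
    }
  }
  return List::create(_["A"] = (double)A, _["B"] = (double)B,
                      _["n_templates"] = nt);
}
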