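#include <Rcpp.h>
using namespace Rcpp;

// Matching statistics by longest-common-extension dynamic programming.
// x, y are integer-coded sequences (A=1, C=2, G=3, T=4, N/other=0).
// l[i] = length of the longest substring of x starting at i that occurs
// anywhere in y. Code 0 (ambiguity) never matches, not even another 0.
// O(n*m) time, O(m) memory.
// [[Rcpp::export]]
IntegerVector matching_stats_cpp(IntegerVector x, IntegerVector y) {
  const int n = x.size(), m = y.size();
  IntegerVector l(n);
  const int *px = INTEGER(x), *py = INTEGER(y);
  int *pl = INTEGER(l);
  std::vector<int> buf1(m + 1, 0), buf2(m + 1, 0);
  int *cur = buf1.data(), *nxt = buf2.data();
  for (int i = n - 1; i >= 0; --i) {
    const int xi = px[i];
    int best = 0;
    if (xi == 0) {
      std::fill(cur, cur + m, 0);
    } else {
      for (int j = m - 1; j >= 0; --j) {
        const int v = (xi == py[j]) ? nxt[j + 1] + 1 : 0;
        cur[j] = v;
        if (v > best) best = v;
      }
    }
    pl[i] = best;
    std::swap(cur, nxt);
  }
  return l;
}
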