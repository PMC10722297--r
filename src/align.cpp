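// Needleman-Wunsch global alignment with match +1, mismatch 0, linear gap -1.
// Identity = 100 * matches / alignment columns of one optimal-score
// alignment (traceback prefers diagonal, then up, then left).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_global_identity(std::string s1, std::string s2) {
  int n = (int)s1.size(), m = (int)s2.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback matrix: 0 diag, 1 up (gap in s2), 2 left (gap in s1)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = -j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sc_d = prev[j - 1] + (s1[i - 1] == s2[j - 1] ? 1 : 0);
      int sc_u = prev[j] - 1;
      int sc_l = cur[j - 1] - 1;
      int best = sc_d; unsigned char dir = 0;
      if (sc_u > best) { best = sc_u; dir = 1; }
      if (sc_l > best) { best = sc_l; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (s1[i - 1] == s2[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  return NumericVector::create(
      Named("identity") = 100.0 * matches / columns,
      Named("score") = (double)score,
      Named("matches") = (double)matches,
      Named("columns") = (double)columns);
}
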