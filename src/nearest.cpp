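#include <Rcpp.h>
using namespace Rcpp;

// Exact nearest neighbour of every row of `src` among the rows of `tgt`.
// Brute force: deterministic, ties broken by the lowest target index.
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export]]
List nn_exact(NumericMatrix src, NumericMatrix tgt) {
  const int n = src.nrow(), m = tgt.nrow();
  if (m == 0) stop("target cloud is empty");
  IntegerVector idx(n);
  NumericVector dist(n);
  const double* s = REAL(src);
  const double* t = REAL(tgt);
  for (int i = 0; i < n; ++i) {
    const double sx = s[i], sy = s[i + n], sz = s[i + 2 * n];
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = t[j] - sx;
      const double dy = t[j + m] - sy;
      const double dz = t[j + 2 * m] - sz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {  // strict '<' keeps the lowest index on ties
        best = d2;
        bestj = j;
      }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
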