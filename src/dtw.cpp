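#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with the symmetric1 step pattern and no window:
// D[i,j] = cost[i,j] + min(D[i-1,j], D[i,j-1], D[i-1,j-1]).
// [[Rcpp::export(name = ".dtw_from_cost")]]
double dtw_from_cost(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  std::vector<double> prev(m), cur(m);
  prev[0] = cost(0, 0);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + cost(0, j);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + cost(i, 0);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = best + cost(i, j);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
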