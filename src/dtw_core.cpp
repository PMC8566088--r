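#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-cost recursion over a precomputed local-cost matrix, with
// backtracking. Boundary cells accumulate along their only predecessor;
// D(1,1) = c(1,1). Backtracking ties prefer the diagonal step, then
// (j-1,i), then (j,i-1), for a deterministic path.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix cost) {
  const int J = cost.nrow();
  const int I = cost.ncol();
  NumericMatrix D(J, I);
  D(0, 0) = cost(0, 0);
  for (int j = 1; j < J; ++j) D(j, 0) = D(j - 1, 0) + cost(j, 0);
  for (int i = 1; i < I; ++i) D(0, i) = D(0, i - 1) + cost(0, i);
  for (int j = 1; j < J; ++j) {
    for (int i = 1; i < I; ++i) {
      double m = D(j - 1, i - 1);
      if (D(j - 1, i) < m) m = D(j - 1, i);
      if (D(j, i - 1) < m) m = D(j, i - 1);
      D(j, i) = m + cost(j, i);
    }
  }
  // backtrack from (J, I)
  std::vector<int> pj, pi;
  int j = J - 1, i = I - 1;
  pj.push_back(j + 1);
  pi.push_back(i + 1);
  while (j > 0 || i > 0) {
    if (j == 0) {
      --i;
    } else if (i == 0) {
      --j;
    } else {
      double d = D(j - 1, i - 1), u = D(j - 1, i), l = D(j, i - 1);
      if (d <= u && d <= l) {
        --j; --i;
      } else if (u <= l) {
        --j;
      } else {
        --i;
      }
    }
    pj.push_back(j + 1);
    pi.push_back(i + 1);
  }
  std::reverse(pj.begin(), pj.end());
  std::reverse(pi.begin(), pi.end());
  const int K = (int) pj.size();
  IntegerMatrix path(K, 2);
  for (int k = 0; k < K; ++k) {
    path(k, 0) = pj[k];
    path(k, 1) = pi[k];
  }
  return List::create(_["cumulative_cost"] = D(J - 1, I - 1),
                      _["path"] = path);
}
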