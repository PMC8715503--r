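#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

// Minimum-cost bipartite assignment (Hungarian algorithm, potential /
// shortest-augmenting-path formulation) for a dense rectangular cost matrix
// with nrow <= ncol. Every row is assigned to a distinct column; the sum of
// the chosen costs is minimal. O(n^2 m).
//
// Returns the 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector lsap_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (n == 0 || m == 0) stop("cost matrix must be non-empty");
  if (n > m) stop("lsap_cpp requires nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  // 1-based potentials and matching; p[j] = row matched to column j
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (j1 < 0) stop("assignment failed: non-finite costs?");
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector ans(n, NA_INTEGER);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
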