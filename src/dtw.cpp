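#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with the symmetric step pattern and no slope
// constraint:
//   g(i,j) = min( g(i-1,j) + d, g(i-1,j-1) + 2d, g(i,j-1) + d )
// with g(0,0) = 2 d(0,0) and local cost d(i,j) = |ref_i - query_j|.
// The step taken at each cell is recorded during the forward pass with a
// deterministic tie preference (diagonal, then reference-advance), so
// backtracking is exact and reproducible on plateaus of equal cost.
//
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector ref, NumericVector query) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("empty input series");

  std::vector<double> g((size_t)n * m);
  std::vector<unsigned char> step((size_t)n * m); // 0 diag, 1 ref-adv, 2 query-adv
  auto at = [m](int i, int j) { return (size_t)i * m + j; };

  for (int i = 0; i < n; ++i) {
    const double ri = ref[i];
    for (int j = 0; j < m; ++j) {
      const double d = std::fabs(ri - query[j]);
      if (!R_finite(d)) stop("non-finite values in input series");
      if (i == 0 && j == 0) {
        g[0] = 2.0 * d;
        step[0] = 0;
      } else if (i == 0) {
        g[at(0, j)] = g[at(0, j - 1)] + d;
        step[at(0, j)] = 2;
      } else if (j == 0) {
        g[at(i, 0)] = g[at(i - 1, 0)] + d;
        step[at(i, 0)] = 1;
      } else {
        double best = g[at(i - 1, j - 1)] + 2.0 * d; // prefer diagonal
        unsigned char s = 0;
        const double up = g[at(i - 1, j)] + d;       // then reference-advance
        if (up < best) { best = up; s = 1; }
        const double left = g[at(i, j - 1)] + d;
        if (left < best) { best = left; s = 2; }
        g[at(i, j)] = best;
        step[at(i, j)] = s;
      }
    }
  }

  // backtrack from (n-1, m-1) to (0, 0)
  std::vector<int> ri_path, qi_path;
  ri_path.reserve(n + m);
  qi_path.reserve(n + m);
  int i = n - 1, j = m - 1;
  while (true) {
    ri_path.push_back(i + 1); // 1-based for R
    qi_path.push_back(j + 1);
    if (i == 0 && j == 0) break;
    switch (step[at(i, j)]) {
    case 0: --i; --j; break;
    case 1: --i; break;
    default: --j; break;
    }
  }
  std::reverse(ri_path.begin(), ri_path.end());
  std::reverse(qi_path.begin(), qi_path.end());

  const double total = g[at(n - 1, m - 1)];
  return List::create(_["ref_idx"] = wrap(ri_path),
                      _["query_idx"] = wrap(qi_path),
                      _["total_cost"] = total,
                      _["normalized_cost"] = total / (double)(n + m));
}
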