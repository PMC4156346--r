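#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Cumulative ordered-pair counts within each radius of a sorted grid.
// Returns, for each s in s_grid (ascending), the number of ordered pairs
// (i, j), i != j, with d(i, j) <= s. Points must be sorted by y (the R
// wrapper does this): the inner scan then stops as soon as the y-gap
// exceeds the largest radius, so the cost is n times the neighbour count
// rather than n^2 — fast for the tens of thousands of points in a
// constant-density strip.
// [[Rcpp::export]]
NumericVector pair_counts_within(NumericVector x, NumericVector y,
                                 NumericVector s_grid) {
  const int n = x.size();
  const int m = s_grid.size();
  std::vector<double> s2(m);
  for (int k = 0; k < m; ++k) {
    if (k > 0 && s_grid[k] <= s_grid[k - 1])
      stop("s_grid must be strictly increasing");
    s2[k] = s_grid[k] * s_grid[k];
  }
  for (int i = 1; i < n; ++i)
    if (y[i] < y[i - 1]) stop("points must be sorted by y");
  const double smax = s_grid[m - 1];
  const double smax2 = s2[m - 1];
  NumericVector counts(m);
  for (int i = 1; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i - 1; j >= 0; --j) {
      const double dy = yi - y[j];
      if (dy > smax) break;
      const double dx = xi - x[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 <= smax2) {
        const int k = std::lower_bound(s2.begin(), s2.end(), d2) - s2.begin();
        counts[k] += 2.0; // both orderings of the pair
      }
    }
  }
  for (int k = 1; k < m; ++k) counts[k] += counts[k - 1];
  return counts;
}
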