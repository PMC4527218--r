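#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation scan: over all arcs (i, j] (0 <= i < j <= n,
// excluding the full circle) whose width and complement are both at least
// min_width, find the arc maximizing the two-sample t-like statistic
// comparing the arc mean with the mean of the rest of the segment.
// Returns {stat, i, j}. stat is 0 when the segment is constant.
static void scan_max(const std::vector<double> &x, int min_width,
                     double &best, int &bi, int &bj) {
  const int n = (int)x.size();
  best = 0.0; bi = -1; bj = -1;
  if (n < 2 * min_width) return;
  std::vector<double> cs(n + 1, 0.0);
  double ss = 0.0;
  for (int t = 0; t < n; ++t) { cs[t + 1] = cs[t] + x[t]; ss += x[t] * x[t]; }
  const double tot = cs[n];
  const double var = (ss - tot * tot / n) / n; // population variance
  if (var <= 0) return;
  const double sdev = std::sqrt(var);
  for (int i = 0; i <= n - 1; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      if (i == 0 && j == n) continue;
      const int k = j - i, comp = n - k;
      if (k < min_width || comp < min_width) continue;
      const double arc = cs[j] - cs[i];
      const double d = arc / k - (tot - arc) / comp;
      const double stat = std::fabs(d) / (sdev * std::sqrt(1.0 / k + 1.0 / comp));
      if (stat > best) { best = stat; bi = i; bj = j; }
    }
  }
}

// Permutation p-value for the observed max statistic with sequential early
// stopping: once the exceedance count guarantees p > alpha the remaining
// permutations cannot change the accept/reject decision.
static double perm_pvalue(std::vector<double> x, double observed,
                          int nperm, double alpha, int min_width) {
  const int n = (int)x.size();
  const int stop_at = (int)std::floor(alpha * nperm) + 1;
  int exceed = 0, done = 0;
  double best; int bi, bj;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG (deterministic under set.seed)
    for (int t = n - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(x[t], x[u]);
    }
    scan_max(x, min_width, best, bi, bj);
    ++done;
    if (best >= observed) {
      ++exceed;
      if (exceed >= stop_at) break;
    }
  }
  return (double)exceed / (double)done;
}

static void segment_recurse(const std::vector<double> &x, int lo, int hi,
                            double alpha, int nperm, int min_width,
                            std::vector<int> &bounds) {
  const int n = hi - lo + 1;
  if (n < 2 * min_width) return;
  std::vector<double> seg(x.begin() + lo, x.begin() + hi + 1);
  double best; int bi, bj;
  scan_max(seg, min_width, best, bi, bj);
  if (bi < 0 || best <= 0) return;
  double p = perm_pvalue(seg, best, nperm, alpha, min_width);
  if (p > alpha) return;
  // change-points at lo+bi-1 | lo+bi and lo+bj-1 | lo+bj (0-based, in x)
  std::vector<std::pair<int, int> > parts;
  int a = lo + bi, b = lo + bj; // arc occupies [a, b-1]
  if (bi > 0) bounds.push_back(a - 1);
  if (bj < n) bounds.push_back(b - 1);
  if (bi > 0) parts.push_back(std::make_pair(lo, a - 1));
  parts.push_back(std::make_pair(a, b - 1));
  if (bj < n) parts.push_back(std::make_pair(b, hi));
  for (size_t t = 0; t < parts.size(); ++t) {
    segment_recurse(x, parts[t].first, parts[t].second,
                    alpha, nperm, min_width, bounds);
  }
}

// [[Rcpp::export(name = ".cbs_segment_series")]]
IntegerVector cbs_segment_series(NumericVector x, double alpha, int nperm,
                                 int min_width) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> bounds;
  segment_recurse(v, 0, n - 1, alpha, nperm, min_width, bounds);
  bounds.push_back(n - 1);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  // return 1-based end indices of segments
  IntegerVector out(bounds.size());
  for (size_t t = 0; t < bounds.size(); ++t) out[t] = bounds[t] + 1;
  return out;
}
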