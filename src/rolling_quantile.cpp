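#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trailing-window rolling quantile with an expanding window at the start.
//
// At sample n (1-based) the window holds x[max(1, n-w+1) .. n].  The quantile
// follows stats::quantile type 7: h = (m-1)*q for a window of m samples, and
// the result interpolates linearly between order statistics floor(h)+1 and
// floor(h)+2.  Values are rank-compressed once and counted in a Fenwick tree,
// so each step is O(log n) for insert, delete and order-statistic query.

namespace {

struct Fenwick {
  std::vector<int> t;
  int n, logn;
  explicit Fenwick(int n_) : t(n_ + 1, 0), n(n_) {
    logn = 0;
    while ((1 << (logn + 1)) <= n) ++logn;
  }
  void add(int i, int v) {
    for (; i <= n; i += i & -i) t[i] += v;
  }
  // index of the k-th smallest stored element (1-based k)
  int kth(int k) const {
    int pos = 0;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      if (pos + pw <= n && t[pos + pw] < k) {
        pos += pw;
        k -= t[pos];
      }
    }
    return pos + 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".roll_quantile_trailing")]]
NumericVector roll_quantile_trailing(NumericVector x, int w, double q) {
  const int n = x.size();
  if (n == 0) return NumericVector(0);
  if (w < 1) stop("window width must be >= 1 sample");
  if (!(q > 0.0 && q < 1.0)) stop("quantile must lie strictly in (0, 1)");

  // rank-compress
  std::vector<double> sorted(x.begin(), x.end());
  for (double v : sorted)
    if (!R_finite(v)) stop("input contains non-finite values");
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  const int m = static_cast<int>(sorted.size());

  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i)
    rank[i] = static_cast<int>(std::lower_bound(sorted.begin(), sorted.end(),
                                                x[i]) - sorted.begin()) + 1;

  Fenwick fw(m);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    fw.add(rank[i], 1);
    if (i - w >= 0) fw.add(rank[i - w], -1);
    const int sz = std::min(i + 1, w);
    const double h = (sz - 1) * q;
    const int lo = static_cast<int>(std::floor(h));
    const double frac = h - lo;
    double v = sorted[fw.kth(lo + 1) - 1];
    if (frac > 0.0) {
      const double v2 = sorted[fw.kth(lo + 2) - 1];
      v += frac * (v2 - v);
    }
    out[i] = v;
  }
  return out;
}
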