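#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dip statistic for unimodality, computed from its definition: the smallest
// sup-norm half-band t such that some unimodal (convex-then-concave) CDF
// stays within t of the empirical CDF everywhere. For a step ECDF with
// unique points x_i and right values F_i (F_{-1} = 0), a continuous
// candidate CDF must pass through bands [F_i - t, F_{i-1} + t] at the data
// points; a jump is admissible only at the mode. Feasibility of a convex
// nondecreasing segment over a prefix is equivalent to the greatest convex
// minorant of the upper band staying above the lower band; the concave
// suffix is the mirrored problem. The smallest feasible t is found by
// bisection.

// Convex function within bands [a_i, b_i] exists over points 0..k-1?
static bool convex_feasible(const std::vector<double>& x,
                            const std::vector<double>& a,
                            const std::vector<double>& b, int k) {
  if (k <= 0) return true;
  std::vector<int> h;
  h.reserve(k);
  for (int i = 0; i < k; ++i) {
    if (b[i] < a[i]) return false; // empty band: off-mode atom too large
    while ((int)h.size() >= 2) {
      int j = h[h.size() - 1], l = h[h.size() - 2];
      double cross = (b[i] - b[l]) * (x[j] - x[l]) -
                     (b[j] - b[l]) * (x[i] - x[l]);
      if (cross <= 0) h.pop_back(); else break;
    }
    h.push_back(i);
  }
  int seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < (int)h.size() && x[h[seg + 1]] <= x[i]) ++seg;
    double v;
    if (seg + 1 >= (int)h.size()) {
      v = b[h[seg]];
    } else {
      int l = h[seg], r = h[seg + 1];
      v = b[l] + (b[r] - b[l]) * (x[i] - x[l]) / (x[r] - x[l]);
    }
    if (v < a[i] - 1e-12) return false;
  }
  return true;
}

// largest feasible prefix length (monotone in k), by binary search
static int max_prefix(const std::vector<double>& x,
                      const std::vector<double>& a,
                      const std::vector<double>& b) {
  int m = (int)x.size();
  int lo = 0, hi = m;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (convex_feasible(x, a, b, mid)) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector xs, NumericVector Fs) {
  int m = xs.size();
  if (m <= 1) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> F(Fs.begin(), Fs.end());

  // reflected coordinates for the concave (suffix) side
  std::vector<double> xr(m), ar_up(m), br_up(m);

  double lo = 0.0, hi = 0.5;
  for (int iter = 0; iter < 50; ++iter) {
    double t = 0.5 * (lo + hi);
    std::vector<double> a(m), b(m);
    for (int i = 0; i < m; ++i) {
      a[i] = F[i] - t;
      b[i] = (i == 0 ? 0.0 : F[i - 1]) + t;
    }
    int P = max_prefix(x, a, b);
    // concave over suffix of length s == convex over reflected prefix:
    // x' = -x reversed, lower' = -b reversed, upper' = -a reversed
    for (int i = 0; i < m; ++i) {
      int j = m - 1 - i;
      xr[i] = -x[j];
      ar_up[i] = -b[j]; // new lower bound
      br_up[i] = -a[j]; // new upper bound
    }
    int S = max_prefix(xr, ar_up, br_up);
    bool feasible = (m - 1 - S) <= P; // one free mode point in between
    if (feasible) hi = t; else lo = t;
  }
  return 0.5 * (lo + hi);
}
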