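// Hartigan & Hartigan dip statistic: maximum distance between the ECDF and
// the closest unimodal CDF, computed by the greatest-convex-minorant /
// least-concave-majorant iteration. Count units internally; the returned
// dip is in ECDF units (divide by 2n at the end).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// lower convex hull vertex indices of points (x[i], i), i in [lo, hi]
static void gcm_hull(const std::vector<double> &x, int lo, int hi,
                     std::vector<int> &v) {
  v.clear();
  v.push_back(lo);
  for (int i = lo + 1; i <= hi; ++i) {
    while (v.size() >= 2) {
      int j = v[v.size() - 1], k = v[v.size() - 2];
      // keep j while slope(k->j) < slope(j->i)
      if ((x[i] - x[j]) * (j - k) < (x[j] - x[k]) * (i - j)) break;
      v.pop_back();
    }
    v.push_back(i);
  }
}

// upper concave hull
static void lcm_hull(const std::vector<double> &x, int lo, int hi,
                     std::vector<int> &v) {
  v.clear();
  v.push_back(lo);
  for (int i = lo + 1; i <= hi; ++i) {
    while (v.size() >= 2) {
      int j = v[v.size() - 1], k = v[v.size() - 2];
      if ((x[i] - x[j]) * (j - k) > (x[j] - x[k]) * (i - j)) break;
      v.pop_back();
    }
    v.push_back(i);
  }
}

// linear interpolation of the count value between hull vertices j1, j2
static double interp_cnt(const std::vector<double> &x, int j1, int j2,
                         double xt) {
  if (x[j2] == x[j1]) return (double)j2;
  return j1 + (xt - x[j1]) * (double)(j2 - j1) / (x[j2] - x[j1]);
}

// x must be sorted ascending; returns the dip statistic
static double dip_sorted(const std::vector<double> &x) {
  int n = (int)x.size();
  if (n < 2) return 0.0;
  if (x[0] == x[n - 1]) return 0.0;
  int low = 0, high = n - 1;
  double dipc = 1.0; // in units of 2n * dip
  std::vector<int> g, l;
  for (;;) {
    gcm_hull(x, low, high, g);
    lcm_hull(x, low, high, l);
    double d = 0.0;
    int nlow = low, nhigh = high;
    if (g.size() > 2 || l.size() > 2) {
      // deviation at each lcm vertex j: (j + 1) - gcm(x_j)
      size_t gi = 0;
      for (size_t t = 0; t < l.size(); ++t) {
        int j = l[t];
        while (gi + 1 < g.size() && g[gi + 1] <= j) ++gi;
        int g1 = g[gi];
        int g2 = g[std::min(gi + 1, g.size() - 1)];
        double gv = (g2 == g1) ? (double)g1 : interp_cnt(x, g1, g2, x[j]);
        double dev = j + 1 - gv;
        if (dev > d) { d = dev; nlow = g1; nhigh = j; }
      }
      // deviation at each gcm vertex j: lcm(x_j) - j + 1
      size_t li = 0;
      for (size_t t = 0; t < g.size(); ++t) {
        int j = g[t];
        while (li + 1 < l.size() && l[li + 1] <= j) ++li;
        int l1 = l[li];
        int l2 = l[std::min(li + 1, l.size() - 1)];
        double lv = (l2 == l1) ? (double)l1 : interp_cnt(x, l1, l2, x[j]);
        double dev = lv - j + 1;
        if (dev > d) { d = dev; nlow = j; nhigh = l2; }
      }
    } else {
      d = 1.0;
    }
    if (d <= dipc) break;
    // deviation of the ECDF from the gcm over [low, nlow]
    double dl = 0.0;
    for (size_t s = 0; s + 1 < g.size() && g[s] < nlow; ++s) {
      int j1 = g[s], j2 = g[s + 1];
      if (j2 > nlow) break;
      for (int jb = j1; jb <= j2; ++jb) {
        double gv = interp_cnt(x, j1, j2, x[jb]);
        double dev = jb + 1 - gv;
        if (dev > dl) dl = dev;
      }
    }
    // deviation of the ECDF from the lcm over [nhigh, high]
    double du = 0.0;
    for (size_t s = 0; s + 1 < l.size(); ++s) {
      int j1 = l[s], j2 = l[s + 1];
      if (j2 <= nhigh) continue;
      if (j1 < nhigh) continue;
      for (int jb = j1; jb <= j2; ++jb) {
        double lv = interp_cnt(x, j1, j2, x[jb]);
        double dev = lv - jb + 1;
        if (dev > du) du = dev;
      }
    }
    if (dl > dipc) dipc = dl;
    if (du > dipc) dipc = du;
    if (nlow == low && nhigh == high) break;
    low = nlow;
    high = nhigh;
  }
  return dipc / (2.0 * n);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector values) {
  std::vector<double> x(values.begin(), values.end());
  std::sort(x.begin(), x.end());
  return dip_sorted(x);
}

// Monte-Carlo null distribution of the dip for samples of size n from the
// uniform distribution; uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int n_mc) {
  NumericVector out(n_mc);
  std::vector<double> x((size_t)n);
  for (int r = 0; r < n_mc; ++r) {
    for (int i = 0; i < n; ++i) x[i] = unif_rand();
    std::sort(x.begin(), x.end());
    out[r] = dip_sorted(x);
  }
  return out;
}
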