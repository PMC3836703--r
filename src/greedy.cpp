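#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Incremental Pearson state over a growing index set.
struct CorrState {
  double sx = 0.0, sy = 0.0, sxx = 0.0, syy = 0.0, sxy = 0.0;
  int n = 0;
  void add(double x, double y) {
    sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y; ++n;
  }
  // r from the product-moment sums; 0 when a margin is degenerate
  double r() const {
    double vx = n * sxx - sx * sx;
    double vy = n * syy - sy * sy;
    if (vx <= 0.0 || vy <= 0.0) return 0.0;
    double r = (n * sxy - sx * sy) / std::sqrt(vx * vy);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    return r;
  }
  // two-sided p from the t transform with n - 2 df
  double p() const {
    if (n < 3) return 1.0;
    double rr = r();
    if (std::fabs(rr) >= 1.0) return 0.0;
    double t = rr * std::sqrt((n - 2) / (1.0 - rr * rr));
    return 2.0 * R::pt(-std::fabs(t), n - 2, 1, 0);
  }
};

// Greedy growth of the correlated subgroup for one miR-gene pair.
//
// Starting from the three seed patients, candidates are visited in scan_order;
// a candidate is sent to the complement only when admitting it would weaken
// the subgroup correlation under the chosen rule:
//   criterion 0 ("corr_and_p"): rejected only if |r| decreases AND the
//     correlation p-value increases (a larger subgroup at similar r gains
//     significance, so informative patients keep joining);
//   criterion 1 ("corr_only"): rejected iff |r| strictly decreases.
// With converge = true, rejected candidates are re-scanned (same relative
// order) until a full pass admits no one; the group only ever grows.
//
// init and scan_order are 0-based; the returned group1 is 1-based.
// [[Rcpp::export(name = ".greedy_core")]]
List greedy_core(NumericVector x, NumericVector y,
                 IntegerVector init, IntegerVector scan_order,
                 int criterion, bool converge, int max_passes) {
  CorrState st;
  std::vector<int> group1(init.begin(), init.end());
  for (int i = 0; i < init.size(); ++i) st.add(x[init[i]], y[init[i]]);
  double cur_r = st.r(), cur_p = st.p();

  std::vector<int> rem(scan_order.begin(), scan_order.end());
  std::vector<double> trace_r, trace_p;
  trace_r.push_back(cur_r); trace_p.push_back(cur_p);

  int passes = 0;
  for (;;) {
    ++passes;
    bool changed = false;
    std::vector<int> rejected;
    rejected.reserve(rem.size());
    for (size_t i = 0; i < rem.size(); ++i) {
      int k = rem[i];
      CorrState tmp = st;
      tmp.add(x[k], y[k]);
      double tr = tmp.r(), tp = tmp.p();
      // |r| comparisons carry a 1e-12 tolerance so exact ties (collinear
      // points) admit regardless of floating-point rounding
      bool r_drops = std::fabs(cur_r) - std::fabs(tr) > 1e-12;
      bool reject;
      if (criterion == 1) {
        reject = r_drops;
      } else {
        reject = r_drops && (cur_p < tp);
      }
      if (reject) {
        rejected.push_back(k);
      } else {
        st = tmp; cur_r = tr; cur_p = tp;
        group1.push_back(k);
        trace_r.push_back(cur_r); trace_p.push_back(cur_p);
        changed = true;
      }
    }
    rem.swap(rejected);
    if (!converge || !changed || rem.empty() || passes >= max_passes) break;
  }

  IntegerVector g1(group1.begin(), group1.end());
  g1 = g1 + 1;
  return List::create(
    _["group1"] = g1,
    _["r"] = cur_r,
    _["p"] = cur_p,
    _["trace_r"] = NumericVector(trace_r.begin(), trace_r.end()),
    _["trace_p"] = NumericVector(trace_p.begin(), trace_p.end()),
    _["passes"] = passes);
}
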