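#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive Gini split search for one numeric feature on a binary outcome.
// Candidate thresholds sit at midpoints of adjacent distinct observed
// values; ties in gain keep the smallest threshold. Gain is the total Gini
// impurity decrease  g(parent) - g(left) - g(right)  with
// g(S) = 2 * pos(S) * neg(S) / |S|, computed over the records with an
// observed value for the feature.

// [[Rcpp::export(name = ".best_split_num_cpp")]]
List best_split_num_cpp(NumericVector x, IntegerVector y, int min_leaf) {
  const int n = x.size();
  if (n < 2 * min_leaf) {
    return List::create(_["found"] = false);
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double tot_pos = 0.0;
  for (int i = 0; i < n; ++i) tot_pos += y[i];
  const double tot_neg = n - tot_pos;
  const double g_parent = 2.0 * tot_pos * tot_neg / n;

  double best_gain = 0.0, best_thr = NA_REAL;
  int best_nl = 0;
  bool found = false;

  double pos_l = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    pos_l += y[ord[k]];
    const int nl = k + 1, nr = n - nl;
    if (x[ord[k]] == x[ord[k + 1]]) continue;
    if (nl < min_leaf || nr < min_leaf) continue;
    const double neg_l = nl - pos_l;
    const double pos_r = tot_pos - pos_l, neg_r = tot_neg - neg_l;
    const double gain = g_parent - 2.0 * pos_l * neg_l / nl
                                 - 2.0 * pos_r * neg_r / nr;
    if (gain > best_gain + 1e-12) {
      best_gain = gain;
      best_thr = 0.5 * (x[ord[k]] + x[ord[k + 1]]);
      best_nl = nl;
      found = true;
    }
  }
  if (!found) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["threshold"] = best_thr,
                      _["gain"] = best_gain, _["n_left"] = best_nl,
                      _["n_right"] = n - best_nl);
}
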