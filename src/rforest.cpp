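// Minimal random-forest regressor (CART, squared-error splits) with
// scikit-learn-style stopping rules: max_depth, min_samples_split,
// min_samples_leaf, mtry features sampled per node, bootstrap rows per tree.
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    threshold.push_back(0.0); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

// Sample k of n feature indices without replacement (partial Fisher-Yates).
static void sample_features(int n, int k, std::vector<int>& out) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& rows, int lo, int hi, int depth,
                 int node, int mtry, int max_depth, int min_split,
                 int min_leaf, TreeBuf& tb) {
  const int n = hi - lo;
  double ysum = 0.0, ysq = 0.0;
  for (int i = lo; i < hi; ++i) { ysum += y[rows[i]]; ysq += y[rows[i]] * y[rows[i]]; }
  tb.value[node] = ysum / n;
  const double node_sse = ysq - ysum * ysum / n;
  if (depth >= max_depth || n < min_split || n < 2 * min_leaf ||
      node_sse <= 1e-12) return;

  std::vector<int> feats;
  sample_features(X.ncol(), mtry, feats);

  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;
  std::vector<std::pair<double, int> > vals(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[lo + i], f), rows[lo + i]);
    std::sort(vals.begin(), vals.end());
    double suml = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      suml += y[vals[i].second];
      const int nl = i + 1, nr = n - nl;
      if (vals[i].first == vals[i + 1].first) continue;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sumr = ysum - suml;
      const double gain = suml * suml / nl + sumr * sumr / nr - ysum * ysum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition rows[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return;  // numerical degeneracy guard

  tb.feature[node] = best_f;
  tb.threshold[node] = best_thr;
  const int nl = tb.add_node(), nr = tb.add_node();
  tb.left[node] = nl; tb.right[node] = nr;
  grow(X, y, rows, lo, mid, depth + 1, nl, mtry, max_depth, min_split,
       min_leaf, tb);
  grow(X, y, rows, mid, hi, depth + 1, nr, mtry, max_depth, min_split,
       min_leaf, tb);
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_split, int min_leaf,
                bool bootstrap = true) {
  const int n = X.nrow();
  List forest(n_trees);
  std::vector<int> rows(n);
  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        rows[i] = j;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    TreeBuf tb;
    const int root = tb.add_node();
    grow(X, y, rows, 0, n, 0, root, mtry, max_depth, min_split, min_leaf, tb);
    forest[t] = List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["value"] = NumericVector(tb.value.begin(), tb.value.end()));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += value[node];
    }
  }
  return out / (double)T;
}
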