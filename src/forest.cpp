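// Binary classification random forest: bootstrap bagging over CART trees
// grown with the Gini criterion, mtry features per node, mean-decrease-Gini
// importance.  Single-threaded and fully deterministic given `seed`.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int var;       // split feature (0-based), -1 for leaf
  double thr;    // split threshold; x <= thr goes left
  int left, right;
  double value;  // proportion of class 1 among training samples in node
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;  // accumulated impurity decrease
  int n_total;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, std::mt19937& rng_, std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
        importance(imp), n_total(X_.nrow()) {}

  static double gini(int n1, int n) {
    if (n == 0) return 0.0;
    double p = (double)n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    int n1 = 0;
    for (int k = lo; k < hi; ++k) n1 += y[idx[k]];
    double node_value = (double)n1 / n;
    double g_parent = gini(n1, n);

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, node_value});
    if (n < 2 * min_node || n1 == 0 || n1 == n) return me;

    // sample mtry distinct candidate features (partial Fisher-Yates)
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    double best_gain = 1e-12;
    int best_var = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> xv(n);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int k = 0; k < n; ++k)
        xv[k] = {X(idx[lo + k], f), y[idx[lo + k]]};
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      int ln = 0, ln1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        ln++; ln1 += xv[k].second;
        if (xv[k].first == xv[k + 1].first) continue;
        if (ln < min_node || n - ln < min_node) continue;
        double g = g_parent -
                   ((double)ln / n) * gini(ln1, ln) -
                   ((double)(n - ln) / n) * gini(n1 - ln1, n - ln);
        if (g > best_gain) {
          best_gain = g;
          best_var = f;
          best_thr = xv[k].first / 2.0 + xv[k + 1].first / 2.0;
        }
      }
    }
    if (best_var < 0) return me;

    importance[best_var] += best_gain * ((double)n / n_total);

    // partition idx[lo, hi) in place
    int mid = lo;
    for (int k = lo; k < hi; ++k)
      if (X(idx[k], best_var) <= best_thr) std::swap(idx[k], idx[mid++]);
    if (mid == lo || mid == hi) { // numeric ties on the threshold
      nodes[me].var = -1;
      return me;
    }
    nodes[me].var = best_var;
    nodes[me].thr = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].var;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
               ? (int)tree(node, 2)
               : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) idx[k] = boot(rng);
    TreeBuilder tb(X, y, mtry, min_node, rng, importance);
    tb.build(idx, 0, n);
    trees[t] = pack(tb.nodes);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector votes(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      if (tree_predict(tree, X, i) >= 0.5) votes[i] += 1.0;
  }
  for (int i = 0; i < n; ++i) votes[i] /= ntree;
  return votes;
}
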