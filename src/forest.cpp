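// Classification random forest: CART trees on the Gini criterion with
// per-tree bootstrap bagging and per-node feature subsampling (mtry), plus
// mean-decrease-impurity variable importance.  Written against the usual
// Breiman conventions; kept deliberately small (dense numeric features,
// integer class labels).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (0-based), -1 otherwise
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_classes, mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<double>& importance; // accumulated weighted impurity decrease
  double n_root;                   // bootstrap sample size (weights)
  Tree tree;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int ncl, int mtry_,
          int min_node_, int max_depth_, std::mt19937& rng_,
          std::vector<double>& imp, double n_root_)
      : X(X_), y(y_), n_classes(ncl), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_), importance(imp), n_root(n_root_) {}

  static double gini(const std::vector<double>& cnt, double n) {
    if (n <= 0.0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += c * c;
    return 1.0 - s / (n * n);
  }

  int add_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(-1);
    return (int)tree.feature.size() - 1;
  }

  int majority(const std::vector<double>& cnt) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (cnt[c] > cnt[best]) best = c;
    return best;
  }

  // idx: row indices of the bootstrap sample at this node (with repeats)
  int grow(std::vector<int>& idx, int depth) {
    int node = add_node();
    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    double n = (double)idx.size();
    double g_parent = gini(cnt, n);
    bool pure = false;
    for (int c = 0; c < n_classes; ++c)
      if (cnt[c] == n) pure = true;
    if (pure || (int)idx.size() < 2 * min_node ||
        (max_depth > 0 && depth >= max_depth)) {
      tree.pred[node] = majority(cnt);
      return node;
    }

    int d = X.ncol();
    std::vector<int> feats(d);
    for (int j = 0; j < d; ++j) feats[j] = j;
    // partial Fisher-Yates: first mtry entries are the candidates
    for (int j = 0; j < mtry && j < d; ++j) {
      std::uniform_int_distribution<int> u(j, d - 1);
      std::swap(feats[j], feats[u(rng)]);
    }

    int best_f = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<std::pair<double, int>> vals;
    vals.reserve(idx.size());
    for (int jj = 0; jj < mtry && jj < d; ++jj) {
      int f = feats[jj];
      vals.clear();
      for (int i : idx) vals.push_back({X(i, f), y[i]});
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::vector<double> lc(n_classes, 0.0);
      double nl = 0.0;
      for (size_t k = 0; k + 1 < vals.size(); ++k) {
        lc[vals[k].second] += 1.0;
        nl += 1.0;
        if (vals[k].first == vals[k + 1].first) continue;
        if (nl < min_node || n - nl < min_node) continue;
        double gl = 0.0, gr = 0.0, sr = 0.0, sl = 0.0;
        for (int c = 0; c < n_classes; ++c) {
          sl += lc[c] * lc[c];
          double rc = cnt[c] - lc[c];
          sr += rc * rc;
        }
        gl = 1.0 - sl / (nl * nl);
        gr = 1.0 - sr / ((n - nl) * (n - nl));
        double gain = g_parent - (nl * gl + (n - nl) * gr) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = (vals[k].first + vals[k + 1].first) / 2.0;
        }
      }
    }

    if (best_f < 0) {
      tree.pred[node] = majority(cnt);
      return node;
    }
    importance[best_f] += (n / n_root) * best_gain;
    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    // free parent index list memory before recursing is not worth it here
    tree.left[node] = grow(li, depth + 1);
    tree.right[node] = grow(ri, depth + 1);
    return node;
  }
};

int predict_tree(const IntegerVector& feature, const NumericVector& threshold,
                 const IntegerVector& left, const IntegerVector& right,
                 const IntegerVector& pred, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  return pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                int mtry, int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> importance(X.ncol(), 0.0);
  List trees(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    Builder b(X, y, n_classes, mtry, min_node, max_depth, rng, importance,
              (double)n);
    b.grow(idx, 0);
    trees[t] = List::create(
        _["feature"] = wrap(b.tree.feature),
        _["threshold"] = wrap(b.tree.threshold), _["left"] = wrap(b.tree.left),
        _["right"] = wrap(b.tree.right), _["pred"] = wrap(b.tree.pred));
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(importance.begin(), importance.end());
  if (tot > 0)
    for (int j = 0; j < imp.size(); ++j) imp[j] /= tot;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n_classes = as<int>(forest["n_classes"]);
  int n = X.nrow(), T = trees.size();
  IntegerVector out(n);
  std::vector<std::vector<int>> votes(n, std::vector<int>(n_classes, 0));
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"], pred = tr["pred"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i)
      votes[i][predict_tree(feature, threshold, left, right, pred, X, i)]++;
  }
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[i][c] > votes[i][best]) best = c;
    out[i] = best;
  }
  return out;
}
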