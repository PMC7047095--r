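// Classification random forest: CART trees on bootstrap samples with
// per-node random feature subsets (mtry) and Gini impurity splits.
// Implemented in C++ because no forest learner ships with the runtime;
// the two-stage selection and downsampling logic lives in R.
//
// Determinism: bootstrap row indices and one RNG seed per tree are drawn
// in R; inside a tree a single mt19937 stream drives the per-node feature
// subsampling, so a fit is reproducible bit-for-bit.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (majority, lowest index on ties)
};

double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : cnt) {
    double p = static_cast<double>(c) / n;
    s += p * p;
  }
  return 1.0 - s;
}

int majority_class(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = static_cast<int>(k);
  return best;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, max_depth;
  std::mt19937 rng;
  TreeNodes tree;
  std::vector<double>& importance; // accumulated impurity decrease, length p
  double n_root;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_,
          int max_depth_, unsigned seed, std::vector<double>& imp)
      : X(X_), y(y_), K(K_), mtry(mtry_), max_depth(max_depth_), rng(seed),
        importance(imp), n_root(0.0), feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int depth) {
    int n = static_cast<int>(idx.size());
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    double imp_parent = gini_from_counts(cnt, n);

    int node = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(majority_class(cnt));

    if (n < 2 || imp_parent <= 0.0 || depth >= max_depth) return node;

    // sample mtry distinct candidate features (partial Fisher-Yates)
    int p = static_cast<int>(feat_pool.size());
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feat_pool[j], feat_pool[d(rng)]);
    }

    double best_dec = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> left_cnt(K);
    for (int j = 0; j < m; ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(left_cnt.begin(), left_cnt.end(), 0);
      double sum_left_sq = 0.0; // maintain sum of squared counts incrementally
      std::vector<int> right_cnt(cnt);
      double sum_right_sq = 0.0;
      for (int c : cnt) sum_right_sq += static_cast<double>(c) * c;
      for (int i = 0; i < n - 1; ++i) {
        int c = vals[i].second;
        sum_left_sq += 2.0 * left_cnt[c] + 1.0;
        left_cnt[c]++;
        sum_right_sq -= 2.0 * right_cnt[c] - 1.0;
        right_cnt[c]--;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double gl = 1.0 - sum_left_sq / (static_cast<double>(nl) * nl);
        double gr = 1.0 - sum_right_sq / (static_cast<double>(nr) * nr);
        double dec = imp_parent -
                     (static_cast<double>(nl) / n) * gl -
                     (static_cast<double>(nr) / n) * gr;
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_f = f;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return node;

    importance[best_f] += (n / n_root) * best_dec;

    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr)
        lidx.push_back(i);
      else
        ridx.push_back(i);
    }
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(lidx, depth + 1);
    tree.right[node] = build(ridx, depth + 1);
    return node;
  }
};

int tree_predict_one(const IntegerVector& feature, const NumericVector& threshold,
                     const IntegerVector& left, const IntegerVector& right,
                     const IntegerVector& pred, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return pred[node];
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes, int ntree,
                int mtry, IntegerMatrix boot_idx, IntegerVector tree_seeds,
                int max_depth = 64) {
  int p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    Builder b(X, y, n_classes, mtry, max_depth,
              static_cast<unsigned>(tree_seeds[t]), importance);
    std::vector<int> idx(boot_idx.nrow());
    for (int i = 0; i < boot_idx.nrow(); ++i) idx[i] = boot_idx(i, t);
    b.n_root = static_cast<double>(idx.size());
    b.build(idx, 0);
    trees[t] = List::create(_["feature"] = wrap(b.tree.feature),
                            _["threshold"] = wrap(b.tree.threshold),
                            _["left"] = wrap(b.tree.left),
                            _["right"] = wrap(b.tree.right),
                            _["pred"] = wrap(b.tree.pred));
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericMatrix rf_votes_cpp(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow();
  int ntree = trees.size();
  NumericMatrix votes(n, n_classes);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      votes(i, tree_predict_one(feature, threshold, left, right, pred, X, i)) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_classes; ++k) votes(i, k) /= ntree;
  return votes;
}
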