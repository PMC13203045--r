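#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bagged regression forest (CART, variance-reduction splits) used as the
// fixed-effect learner inside the mixed-effects random forest, inside Boruta,
// and for permutation importance. All randomness comes from R's RNG so that
// set.seed() on the R side gives full determinism.

namespace {

struct Tree {
  std::vector<int> feature;      // -1 => leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaf mean (also stored for internal nodes)
};

inline int rand_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

double tree_predict_one(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  }
  return t.value[node];
}

// predict one row where a single feature's value is overridden (for
// OOB permutation importance without materialising a permuted matrix)
double tree_predict_override(const Tree& t, const NumericMatrix& X, int row,
                             int f_over, double x_over) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    double x = (f == f_over) ? x_over : X(row, f);
    node = (x <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

class Builder {
public:
  Builder(const NumericMatrix& X, const std::vector<double>& y, int mtry,
          int min_leaf)
      : X_(X), y_(y), mtry_(mtry), min_leaf_(min_leaf), p_(X.ncol()) {
    feat_pool_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
  }

  Tree grow(std::vector<int>& idx) {
    tree_ = Tree();
    build(idx, 0, (int)idx.size());
    return tree_;
  }

private:
  const NumericMatrix& X_;
  const std::vector<double>& y_;
  int mtry_, min_leaf_, p_;
  std::vector<int> feat_pool_;
  Tree tree_;
  std::vector<std::pair<double, double>> buf_; // (x, y) pairs for sorting

  int new_node(double val) {
    tree_.feature.push_back(-1);
    tree_.threshold.push_back(0.0);
    tree_.left.push_back(-1);
    tree_.right.push_back(-1);
    tree_.value.push_back(val);
    return (int)tree_.feature.size() - 1;
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int i = lo; i < hi; ++i) {
      double v = y_[idx[i]];
      sum += v;
      sumsq += v * v;
    }
    double mean = sum / n;
    int node = new_node(mean);
    if (n < 2 * min_leaf_ || sumsq - sum * sum / n < 1e-12) return node;

    // sample mtry candidate features (partial Fisher-Yates)
    int best_f = -1;
    double best_gain = sum * sum / n; // parent score S^2/n; children must beat
    double best_thr = 0.0;
    for (int k = 0; k < mtry_; ++k) {
      int swap_with = k + rand_int(p_ - k);
      std::swap(feat_pool_[k], feat_pool_[swap_with]);
      int f = feat_pool_[k];

      buf_.clear();
      for (int i = lo; i < hi; ++i)
        buf_.push_back(std::make_pair(X_(idx[i], f), y_[idx[i]]));
      std::sort(buf_.begin(), buf_.end());
      if (buf_.front().first == buf_.back().first) continue;

      double sl = 0.0;
      for (int s = 1; s < n; ++s) {
        sl += buf_[s - 1].second;
        if (s < min_leaf_ || n - s < min_leaf_) continue;
        if (buf_[s - 1].first == buf_[s].first) continue;
        double sr = sum - sl;
        double gain = sl * sl / s + sr * sr / (n - s);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = buf_[s - 1].first +
                     0.5 * (buf_[s].first - buf_[s - 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    // partition idx[lo,hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return node; // numerical guard

    tree_.feature[node] = best_f;
    tree_.threshold[node] = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    tree_.left[node] = l;
    tree_.right[node] = r;
    return node;
  }
};

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_leaf) {
  RNGScope scope;
  int n = X.nrow();
  std::vector<double> yv = as<std::vector<double>>(y);
  IntegerMatrix inbag(n, n_trees);
  List trees(n_trees);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  Builder builder(X, yv, mtry, min_leaf);

  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = rand_int(n);
      idx[i] = k;
      inbag(k, b) += 1;
    }
    Tree t = builder.grow(idx);
    for (int i = 0; i < n; ++i) {
      if (inbag(i, b) == 0) {
        oob_sum[i] += tree_predict_one(t, X, i);
        oob_cnt[i] += 1;
      }
    }
    trees[b] = tree_to_list(t);
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];

  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["oob_pred"] = oob_pred);
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// Per-tree, per-feature OOB permutation importance: increase in OOB MSE when
// the feature's values are shuffled among that tree's OOB samples. Returns a
// n_trees x p matrix; Boruta derives Z-scores from its columns.
// [[Rcpp::export]]
NumericMatrix cpp_rf_oob_importance(List trees, IntegerMatrix inbag,
                                    NumericMatrix X, NumericVector y) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol(), B = trees.size();
  NumericMatrix imp(B, p);
  std::vector<int> oob;
  std::vector<double> base_pred, xperm;

  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m < 2) continue;
    base_pred.resize(m);
    double base_mse = 0.0;
    for (int j = 0; j < m; ++j) {
      base_pred[j] = tree_predict_one(t, X, oob[j]);
      double d = base_pred[j] - y[oob[j]];
      base_mse += d * d;
    }
    base_mse /= m;
    for (int f = 0; f < p; ++f) {
      xperm.resize(m);
      for (int j = 0; j < m; ++j) xperm[j] = X(oob[j], f);
      for (int j = m - 1; j > 0; --j)
        std::swap(xperm[j], xperm[rand_int(j + 1)]);
      double mse = 0.0;
      for (int j = 0; j < m; ++j) {
        double pr = tree_predict_override(t, X, oob[j], f, xperm[j]);
        double d = pr - y[oob[j]];
        mse += d * d;
      }
      mse /= m;
      imp(b, f) = mse - base_mse;
    }
  }
  return imp;
}
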