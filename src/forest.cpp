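// CART random forest for binary classification: bootstrap resampling,
// random feature subsets at each node, Gini impurity splits, per-tree
// majority-vote leaves. All randomness comes from R's RNG so a single
// set.seed() makes training bit-reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node ids
  std::vector<int> pred;        // leaf class (0/1)
};

int new_node(Tree &t) {
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0);
  return (int)t.feature.size() - 1;
}

// sample m distinct values from 0..(p-1) via partial Fisher-Yates on R's RNG
void sample_features(std::vector<int> &pool, int m, std::vector<int> &out) {
  int p = (int)pool.size();
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)R_unif_index(p - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_node;
  Tree tree;
  std::vector<int> pool;                    // feature id scratch
  std::vector<std::pair<double, int>> buf;  // (value, label) scratch

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_, int min_node_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_) {
    pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) pool[j] = j;
  }

  int build(std::vector<int> &idx, int lo, int hi) {
    int node = new_node(tree);
    int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
    if (n1 == 0 || n1 == n || n < 2 * min_node || n < 2) {
      tree.pred[node] = (2 * n1 > n) ? 1 : 0;
      return node;
    }

    std::vector<int> feats;
    sample_features(pool, mtry, feats);

    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    const double node_gini = 2.0 * (double)n1 / n * (double)(n - n1) / n;

    for (int f : feats) {
      buf.clear();
      for (int i = lo; i < hi; ++i)
        buf.emplace_back(X(idx[i], f), (int)y[idx[i]]);
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      int left_n = 0, left_n1 = 0;
      for (int i = 0; i + 1 < n; ++i) {
        ++left_n;
        left_n1 += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;  // no split within ties
        int right_n = n - left_n, right_n1 = n1 - left_n1;
        double gl = 2.0 * (double)left_n1 / left_n * (double)(left_n - left_n1) / left_n;
        double gr = 2.0 * (double)right_n1 / right_n * (double)(right_n - right_n1) / right_n;
        double gain = node_gini - ((double)left_n / n) * gl - ((double)right_n / n) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = (buf[i].first + buf[i + 1].first) / 2.0;
        }
      }
    }

    if (best_f < 0) {  // all sampled features constant / no gain
      tree.pred[node] = (2 * n1 > n) ? 1 : 0;
      return node;
    }

    // partition idx[lo,hi) by x <= thr, preserving relative order (stable)
    std::vector<int> l, r;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) l.push_back(idx[i]);
      else r.push_back(idx[i]);
    }
    for (size_t i = 0; i < l.size(); ++i) idx[lo + i] = l[i];
    for (size_t i = 0; i < r.size(); ++i) idx[lo + l.size() + i] = r[i];
    int mid = lo + (int)l.size();

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(idx, lo, mid);
    tree.right[node] = build(idx, mid, hi);
    return node;
  }
};

int predict_one(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

Tree list_to_tree(const List &l) {
  Tree t;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"], pr = l["pred"];
  NumericVector th = l["threshold"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(th.begin(), th.end());
  t.left.assign(le.begin(), le.end());
  t.right.assign(ri.begin(), ri.end());
  t.pred.assign(pr.begin(), pr.end());
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int sample_size, int min_node, bool bootstrap) {
  int n = X.nrow();
  if (n != y.size()) stop("rf_train_cpp: X rows must match length(y)");
  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx;
    if (bootstrap) {
      idx.resize(sample_size);
      for (int i = 0; i < sample_size; ++i) idx[i] = (int)R_unif_index(n);
    } else {
      idx.resize(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Builder bl(X, y, mtry, min_node);
    bl.build(idx, 0, (int)idx.size());
    trees[b] = List::create(
        _["feature"] = IntegerVector(bl.tree.feature.begin(), bl.tree.feature.end()),
        _["threshold"] = NumericVector(bl.tree.threshold.begin(), bl.tree.threshold.end()),
        _["left"] = IntegerVector(bl.tree.left.begin(), bl.tree.left.end()),
        _["right"] = IntegerVector(bl.tree.right.begin(), bl.tree.right.end()),
        _["pred"] = IntegerVector(bl.tree.pred.begin(), bl.tree.pred.end()));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), m = trees.size();
  std::vector<Tree> ts;
  ts.reserve(m);
  for (int b = 0; b < m; ++b) ts.push_back(list_to_tree(trees[b]));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int votes = 0;
    for (int b = 0; b < m; ++b) votes += predict_one(ts[b], X, i);
    out[i] = (double)votes / m;
  }
  return out;
}
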