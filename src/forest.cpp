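// Random forest for binary classification: CART trees with Gini splits,
// bootstrap resampling with out-of-bag tracking, per-split feature
// subsampling (mtry) and accumulated Gini (mean decrease in impurity)
// importance. Self-contained splitmix64 RNG so that (data, seed, n_trees)
// fully determines the model on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); n small, modulo bias negligible but avoid
  // it anyway via rejection
  int unif_int(int n) {
    uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t v;
    do { v = next(); } while (v >= lim);
    return (int)(v % (uint64_t)n);
  }
};

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids
  int pred;         // majority class at node (0/1)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  SplitMix64& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance; // accumulated Gini decrease, length p
  int n_total;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, SplitMix64& rng_, std::vector<double>& imp,
              int n_total_)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
      importance(imp), n_total(n_total_) {}

  int build(std::vector<int>& idx) {
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;
    int node_id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, n1 > n0 ? 1 : 0});
    if (n0 == 0 || n1 == 0 || n < 2 * min_node || n < 2)
      return node_id;

    int p = X.ncol();
    double parent_gini = 1.0 - ((double)n0 * n0 + (double)n1 * n1) /
                               ((double)n * n);
    if (parent_gini <= 0.0) return node_id;

    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rng.unif_int(p - j)]);

    int best_feat = -1;
    double best_dec = 1e-12, best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int fj = 0; fj < m; ++fj) {
      int f = feats[fj];
      for (int i = 0; i < n; ++i)
        vals[i] = { X(idx[i], f), y[idx[i]] };
      std::sort(vals.begin(), vals.end());
      int l0 = 0, l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        if (vals[i].second) ++l1; else ++l0;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        int r0 = n0 - l0, r1 = n1 - l1;
        double gl = 1.0 - ((double)l0 * l0 + (double)l1 * l1) /
                          ((double)nl * nl);
        double gr = 1.0 - ((double)r0 * r0 + (double)r1 * r1) /
                          ((double)nr * nr);
        double dec = parent_gini - ((double)nl / n) * gl -
                                   ((double)nr / n) * gr;
        if (dec > best_dec) {
          best_dec = dec;
          best_feat = f;
          best_thr = vals[i].first +
                     (vals[i + 1].first - vals[i].first) / 2.0;
        }
      }
    }
    if (best_feat < 0) return node_id;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(n);
    right_idx.reserve(n);
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? left_idx : right_idx).push_back(i);
    if (left_idx.empty() || right_idx.empty()) return node_id;

    importance[best_feat] += ((double)n / n_total) * best_dec;
    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    int l = build(left_idx);
    int r = build(right_idx);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

int predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = X(row, f) <= tree(node, 1) ? (int)tree(node, 2)
                                      : (int)tree(node, 3);
  }
  return (int)tree(node, 4);
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "pred");
  return m;
}

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, double seed, bool balanced) {
  int n = X.nrow(), p = X.ncol();
  SplitMix64 rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  // oob_pred(t, i): tree t's vote for row i, NA when i was in-bag
  IntegerMatrix oob_pred(n_trees, n);
  std::fill(oob_pred.begin(), oob_pred.end(), NA_INTEGER);

  std::vector<int> class_idx[2];
  for (int i = 0; i < n; ++i) class_idx[y[i]].push_back(i);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> bag;
    bag.reserve(n);
    std::vector<bool> inbag(n, false);
    if (balanced) {
      // stratified bootstrap: equal draws from each class
      int per_class = n / 2;
      for (int c = 0; c < 2; ++c) {
        int nc = (int)class_idx[c].size();
        for (int i = 0; i < per_class; ++i) {
          int j = class_idx[c][rng.unif_int(nc)];
          bag.push_back(j);
          inbag[j] = true;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        int j = rng.unif_int(n);
        bag.push_back(j);
        inbag[j] = true;
      }
    }
    TreeBuilder tb(X, y, mtry, min_node, rng, importance, (int)bag.size());
    tb.build(bag);
    NumericMatrix tm = pack_tree(tb.nodes);
    trees[t] = tm;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_pred(t, i) = predict_one(tm, X, i);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()),
                      _["oob_pred"] = oob_pred);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector votes(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) votes[i] += predict_one(tm, X, i);
  }
  for (int i = 0; i < n; ++i) votes[i] /= T;
  return votes;
}
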