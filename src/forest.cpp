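#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Bagged CART regression trees.  Each node split uses a random subset of
// `mtry` features (the numFeatures hyperparameter); the forest prediction
// is the arithmetic mean of the per-tree predictions.
//
// Trees are serialized as a numeric matrix with one row per node:
// [var (0-based, -1 = leaf), split, left, right (0-based row), value].

struct NodeTask {
  int row;                      // row in the output matrix
  std::vector<int> samples;     // training-sample indices at this node
};

static double node_mean(const NumericVector& y, const std::vector<int>& s) {
  double m = 0.0;
  for (int i : s) m += y[i];
  return m / s.size();
}

// [[Rcpp::export(name = ".rf_build_tree_cpp")]]
NumericMatrix rf_build_tree_cpp(NumericMatrix X, NumericVector y,
                                IntegerVector sample_idx, int mtry,
                                int min_node, int seed) {
  const int p = X.ncol();
  std::mt19937 rng(seed);
  std::vector<std::vector<double>> nodes;  // rows under construction
  std::vector<NodeTask> stack;

  std::vector<int> root(sample_idx.begin(), sample_idx.end());
  nodes.push_back(std::vector<double>(5, 0.0));
  stack.push_back({0, root});

  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;

  while (!stack.empty()) {
    NodeTask task = stack.back();
    stack.pop_back();
    std::vector<int>& s = task.samples;
    const int ns = (int)s.size();
    double mean = node_mean(y, s);

    bool pure = true;
    for (int i : s)
      if (std::fabs(y[i] - y[s[0]]) > 1e-12) { pure = false; break; }

    if (ns <= min_node || pure) {
      nodes[task.row] = {-1.0, 0.0, -1.0, -1.0, mean};
      continue;
    }

    // choose best split among mtry randomly drawn features
    std::shuffle(feats.begin(), feats.end(), rng);
    int use = std::min(mtry, p);
    double best_gain = -1.0, best_split = 0.0;
    int best_var = -1;

    double sum_all = 0.0;
    for (int i : s) sum_all += y[i];

    std::vector<int> ord(s);
    for (int fi = 0; fi < use; ++fi) {
      int v = feats[fi];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, v) < X(b, v);
      });
      double sum_left = 0.0;
      for (int k = 0; k < ns - 1; ++k) {
        sum_left += y[ord[k]];
        if (X(ord[k + 1], v) - X(ord[k], v) < 1e-12) continue;
        int nl = k + 1, nr = ns - nl;
        double sum_right = sum_all - sum_left;
        // SSE reduction equals sum_l^2/n_l + sum_r^2/n_r - sum^2/n
        double gain = sum_left * sum_left / nl + sum_right * sum_right / nr;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_split = 0.5 * (X(ord[k], v) + X(ord[k + 1], v));
        }
      }
    }

    if (best_var < 0) {  // no valid split among sampled features
      nodes[task.row] = {-1.0, 0.0, -1.0, -1.0, mean};
      continue;
    }

    std::vector<int> left, right;
    for (int i : s) {
      if (X(i, best_var) <= best_split) left.push_back(i);
      else right.push_back(i);
    }
    int lrow = (int)nodes.size();
    nodes.push_back(std::vector<double>(5, 0.0));
    int rrow = (int)nodes.size();
    nodes.push_back(std::vector<double>(5, 0.0));
    nodes[task.row] = {(double)best_var, best_split, (double)lrow,
                       (double)rrow, node_mean(y, s)};
    stack.push_back({lrow, left});
    stack.push_back({rrow, right});
  }

  NumericMatrix out((int)nodes.size(), 5);
  for (size_t r = 0; r < nodes.size(); ++r)
    for (int c = 0; c < 5; ++c) out((int)r, c) = nodes[r][c];
  return out;
}

// [[Rcpp::export(name = ".rf_predict_tree_cpp")]]
NumericVector rf_predict_tree_cpp(NumericMatrix tree, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int row = 0;
    while (tree(row, 0) >= 0) {
      int v = (int)tree(row, 0);
      row = (X(i, v) <= tree(row, 1)) ? (int)tree(row, 2) : (int)tree(row, 3);
    }
    out[i] = tree(row, 4);
  }
  return out;
}
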