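#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Minimal deterministic gradient-boosted decision trees with logistic loss.
// Exact greedy split search (second-order gain, L2 leaf regularisation),
// no row/column subsampling, so identical inputs give identical models.

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x < threshold
  int left, right;
  double value;     // leaf weight
};

static void grow(std::vector<Node> &nodes, int node_id,
                 const NumericMatrix &X,
                 const std::vector<double> &grad,
                 const std::vector<double> &hess,
                 std::vector<int> &rows, int depth, int max_depth,
                 double lambda, double min_child_weight) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += grad[r]; H += hess[r]; }

  double best_gain = 0.0;
  int best_feat = -1;
  double best_thr = 0.0;

  if (depth < max_depth && (int)rows.size() >= 2) {
    const double parent = G * G / (H + lambda);
    const int p = X.ncol();
    std::vector<int> idx(rows);
    for (int j = 0; j < p; ++j) {
      std::sort(idx.begin(), idx.end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b; // stable, deterministic
      });
      double GL = 0.0, HL = 0.0;
      for (size_t k = 0; k + 1 < idx.size(); ++k) {
        GL += grad[idx[k]]; HL += hess[idx[k]];
        double x0 = X(idx[k], j), x1 = X(idx[k + 1], j);
        if (x0 == x1) continue;
        double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + lambda) +
                             GR * GR / (HR + lambda) - parent);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (x0 + x1);
        }
      }
    }
  }

  if (best_feat < 0) { // leaf
    nodes[node_id].feature = -1;
    nodes[node_id].value = -G / (H + lambda);
    return;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, best_feat) < best_thr) lrows.push_back(r); else rrows.push_back(r);
  }
  int li = (int)nodes.size(); nodes.push_back(Node{-1, 0, -1, -1, 0});
  int ri = (int)nodes.size(); nodes.push_back(Node{-1, 0, -1, -1, 0});
  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow(nodes, li, X, grad, hess, lrows, depth + 1, max_depth, lambda,
       min_child_weight);
  grow(nodes, ri, X, grad, hess, rrows, depth + 1, max_depth, lambda,
       min_child_weight);
}

static double tree_predict(const NumericMatrix &tree, const NumericMatrix &X,
                           int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) < tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

static NumericMatrix pack(const std::vector<Node> &nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

// [[Rcpp::export]]
List gbdt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                  int max_depth, double lambda, double min_child_weight,
                  double base_margin) {
  const int n = X.nrow();
  std::vector<double> margin(n, base_margin), grad(n), hess(n);
  List trees(nrounds);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = p - y[i];
      hess[i] = std::max(p * (1.0 - p), 1e-16);
    }
    std::vector<Node> nodes;
    nodes.push_back(Node{-1, 0, -1, -1, 0});
    std::vector<int> rows(all);
    grow(nodes, 0, X, grad, hess, rows, 0, max_depth, lambda,
         min_child_weight);
    NumericMatrix tm = pack(nodes);
    for (int i = 0; i < n; ++i) margin[i] += eta * tree_predict(tm, X, i);
    trees[t] = tm;
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector gbdt_predict_cpp(List trees, NumericMatrix X, double eta,
                               double base_margin, bool margin_only) {
  const int n = X.nrow();
  NumericVector margin(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) margin[i] += eta * tree_predict(tm, X, i);
  }
  if (margin_only) return margin;
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-margin[i]));
  return p;
}
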