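// Depth-limited CART trees used by the ensemble graders.
//
// Two builders over the same flat node layout:
//  * weighted classification trees (Gini impurity) for AdaBoost/RUSBoost
//    and bagging;
//  * second-order regression trees (gradient/hessian, L2-regularized leaf
//    values) for gradient boosting.
//
// A tree is serialized as a NumericMatrix with one row per node:
//   col 0: feature index (-1 for a leaf)
//   col 1: split threshold
//   col 2,3: left/right child row index
//   col 4..: leaf payload (class distribution of length K, or a single
//            regression value)
//
// The builders work on an index range that is partitioned in place and
// reuse one sort buffer, so a fit on a few hundred instances costs well
// under a millisecond; the boosting loops that call them hundreds of times
// per cross-validation fold stay cheap.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;
  double thresh = 0.0;
  int left = -1, right = -1;
  std::vector<double> payload;
};

struct BuilderBase {
  std::vector<double> x;  // column-major n x p copy
  int n, p;
  int max_depth, min_split;
  std::vector<int> idx;
  std::vector<std::pair<double, int>> order;  // reusable sort buffer
  std::vector<Node> nodes;

  BuilderBase(const NumericMatrix& X, int max_depth_, int min_split_)
      : n(X.nrow()), p(X.ncol()), max_depth(max_depth_),
        min_split(min_split_) {
    x.assign(X.begin(), X.end());
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    order.reserve(n);
  }

  double xv(int i, int j) const { return x[(size_t)j * n + i]; }

  // partition idx[lo..hi) by the chosen split; returns the boundary
  int partition(int lo, int hi, int feat, double thresh) {
    int mid = lo;
    for (int r = lo; r < hi; ++r)
      if (xv(idx[r], feat) <= thresh) std::swap(idx[r], idx[mid++]);
    return mid;
  }
};

// ---- weighted classification (Gini) ---------------------------------------

struct ClsBuilder : BuilderBase {
  const int* y;  // 0..K-1
  const double* w;
  int K;
  std::vector<double> counts, lc;

  ClsBuilder(const NumericMatrix& X, const IntegerVector& y_,
             const NumericVector& w_, int K_, int max_depth_, int min_split_)
      : BuilderBase(X, max_depth_, min_split_), y(y_.begin()),
        w(w_.begin()), K(K_), counts(K_), lc(K_) {}

  int build(int lo, int hi, int depth) {
    std::fill(counts.begin(), counts.end(), 0.0);
    double wsum = 0.0;
    for (int r = lo; r < hi; ++r) {
      counts[y[idx[r]]] += w[idx[r]];
      wsum += w[idx[r]];
    }
    int node_id = (int)nodes.size();
    nodes.emplace_back();

    bool pure = false;
    for (int k = 0; k < K; ++k)
      if (counts[k] > 0 && counts[k] >= wsum - 1e-12) pure = true;

    if (depth >= max_depth || hi - lo < min_split || pure || wsum <= 0.0) {
      make_leaf(node_id, wsum);
      return node_id;
    }

    // parent Gini (times wsum): wsum - sum(c_k^2)/wsum
    double parent = wsum;
    for (int k = 0; k < K; ++k) parent -= counts[k] * counts[k] / wsum;
    std::vector<double> parent_counts(counts);

    int best_feat = -1;
    double best_thresh = 0.0, best_impurity = parent - 1e-10;

    for (int j = 0; j < p; ++j) {
      order.clear();
      for (int r = lo; r < hi; ++r)
        order.push_back({xv(idx[r], j), idx[r]});
      std::sort(order.begin(), order.end());
      std::fill(lc.begin(), lc.end(), 0.0);
      double lw = 0.0;
      for (size_t r = 0; r + 1 < order.size(); ++r) {
        int i = order[r].second;
        lc[y[i]] += w[i];
        lw += w[i];
        if (order[r].first >= order[r + 1].first) continue;  // tied values
        double rw = wsum - lw;
        if (lw <= 0.0 || rw <= 0.0) continue;
        double gl = lw, gr = rw;
        for (int k = 0; k < K; ++k) {
          gl -= lc[k] * lc[k] / lw;
          double rc = parent_counts[k] - lc[k];
          gr -= rc * rc / rw;
        }
        if (gl + gr < best_impurity) {
          best_impurity = gl + gr;
          best_feat = j;
          best_thresh = 0.5 * (order[r].first + order[r + 1].first);
        }
      }
    }

    if (best_feat < 0) {
      make_leaf(node_id, wsum);
      return node_id;
    }

    int mid = partition(lo, hi, best_feat, best_thresh);
    int l = build(lo, mid, depth + 1);
    int r = build(mid, hi, depth + 1);
    nodes[node_id].feat = best_feat;
    nodes[node_id].thresh = best_thresh;
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }

  void make_leaf(int node_id, double wsum) {
    Node& nd = nodes[node_id];
    nd.payload.resize(K);
    for (int k = 0; k < K; ++k)
      nd.payload[k] = wsum > 0 ? counts[k] / wsum : 1.0 / K;
  }
};

// ---- second-order regression (gradient boosting) ---------------------------

struct RegBuilder : BuilderBase {
  const double* grad;
  const double* hess;
  double lambda;

  RegBuilder(const NumericMatrix& X, const NumericVector& g,
             const NumericVector& h, double lambda_, int max_depth_,
             int min_split_)
      : BuilderBase(X, max_depth_, min_split_), grad(g.begin()),
        hess(h.begin()), lambda(lambda_) {}

  int build(int lo, int hi, int depth) {
    double G = 0.0, H = 0.0;
    for (int r = lo; r < hi; ++r) {
      G += grad[idx[r]];
      H += hess[idx[r]];
    }
    int node_id = (int)nodes.size();
    nodes.emplace_back();

    if (depth >= max_depth || hi - lo < min_split) {
      nodes[node_id].payload = {-G / (H + lambda)};
      return node_id;
    }

    double parent_score = G * G / (H + lambda);
    int best_feat = -1;
    double best_thresh = 0.0, best_gain = 1e-10;

    for (int j = 0; j < p; ++j) {
      order.clear();
      for (int r = lo; r < hi; ++r)
        order.push_back({xv(idx[r], j), idx[r]});
      std::sort(order.begin(), order.end());
      double GL = 0.0, HL = 0.0;
      for (size_t r = 0; r + 1 < order.size(); ++r) {
        int i = order[r].second;
        GL += grad[i];
        HL += hess[i];
        if (order[r].first >= order[r + 1].first) continue;
        double GR = G - GL, HR = H - HL;
        double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                      parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = j;
          best_thresh = 0.5 * (order[r].first + order[r + 1].first);
        }
      }
    }

    if (best_feat < 0) {
      nodes[node_id].payload = {-G / (H + lambda)};
      return node_id;
    }

    int mid = partition(lo, hi, best_feat, best_thresh);
    int l = build(lo, mid, depth + 1);
    int r = build(mid, hi, depth + 1);
    nodes[node_id].feat = best_feat;
    nodes[node_id].thresh = best_thresh;
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

NumericMatrix serialize(const std::vector<Node>& nodes, int payload_len) {
  NumericMatrix out((int)nodes.size(), 4 + payload_len);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feat;
    out(i, 1) = nodes[i].thresh;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    for (int k = 0; k < payload_len; ++k)
      out(i, 4 + k) = nodes[i].payload.empty() ? 0.0 : nodes[i].payload[k];
  }
  return out;
}

inline int descend(const NumericMatrix& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int j = (int)tree(node, 0);
    node = X(i, j) <= tree(node, 1) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".cart_fit_cls")]]
NumericMatrix cart_fit_cls(NumericMatrix X, IntegerVector y, NumericVector w,
                           int n_classes, int max_depth, int min_split) {
  ClsBuilder b(X, y, w, n_classes, max_depth, min_split);
  b.build(0, X.nrow(), 0);
  return serialize(b.nodes, n_classes);
}

// [[Rcpp::export(name = ".cart_fit_reg")]]
NumericMatrix cart_fit_reg(NumericMatrix X, NumericVector grad,
                           NumericVector hess, double lambda, int max_depth,
                           int min_split) {
  RegBuilder b(X, grad, hess, lambda, max_depth, min_split);
  b.build(0, X.nrow(), 0);
  return serialize(b.nodes, 1);
}

// Leaf payload rows (class distribution or regression value) per instance.
// [[Rcpp::export(name = ".cart_predict")]]
NumericMatrix cart_predict(NumericMatrix tree, NumericMatrix X) {
  int payload_len = tree.ncol() - 4;
  NumericMatrix out(X.nrow(), payload_len);
  for (int i = 0; i < X.nrow(); ++i) {
    int node = descend(tree, X, i);
    for (int k = 0; k < payload_len; ++k) out(i, k) = tree(node, 4 + k);
  }
  return out;
}

// Hard class votes (payload argmax, lowest index wins ties) per instance.
// [[Rcpp::export(name = ".cart_predict_class")]]
IntegerVector cart_predict_class(NumericMatrix tree, NumericMatrix X) {
  int payload_len = tree.ncol() - 4;
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    int node = descend(tree, X, i);
    int best = 0;
    for (int k = 1; k < payload_len; ++k)
      if (tree(node, 4 + k) > tree(node, 4 + best)) best = k;
    out[i] = best;
  }
  return out;
}
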