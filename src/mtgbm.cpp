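#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared-structure multi-task boosting trees.  Gradients/Hessians are
// n x T matrices; masked entries are zero.  Split gain is the summed
// second-order gain over tasks; leaf values are per-task Newton steps
// with L1 soft-thresholding.

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

static Split scan_split(const NumericMatrix& X, const NumericMatrix& G,
                        const NumericMatrix& H,
                        const std::vector<int>& rows,
                        double lambda2, int min_child) {
  const int T = G.ncol(), p = X.ncol();
  const int n = (int)rows.size();
  Split best;
  if (n < 2 * min_child) return best;
  std::vector<double> Gtot(T, 0.0), Htot(T, 0.0);
  for (int t = 0; t < T; ++t)
    for (int i : rows) { Gtot[t] += G(i, t); Htot[t] += H(i, t); }
  double parent = 0.0;
  for (int t = 0; t < T; ++t)
    if (Htot[t] + lambda2 > 0)
      parent += Gtot[t] * Gtot[t] / (Htot[t] + lambda2);
  std::vector<std::pair<double, int>> vals(n);
  std::vector<double> GL(T), HL(T);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) vals[i] = {X(rows[i], f), rows[i]};
    std::stable_sort(vals.begin(), vals.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       return a.first < b.first;
                     });
    std::fill(GL.begin(), GL.end(), 0.0);
    std::fill(HL.begin(), HL.end(), 0.0);
    for (int i = 0; i < n - 1; ++i) {
      const int r = vals[i].second;
      for (int t = 0; t < T; ++t) { GL[t] += G(r, t); HL[t] += H(r, t); }
      if (!(vals[i + 1].first > vals[i].first)) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_child || nr < min_child) continue;
      double gain = -parent;
      for (int t = 0; t < T; ++t) {
        const double GR = Gtot[t] - GL[t], HR = Htot[t] - HL[t];
        if (HL[t] + lambda2 > 0) gain += GL[t] * GL[t] / (HL[t] + lambda2);
        if (HR + lambda2 > 0) gain += GR * GR / (HR + lambda2);
      }
      if (gain > best.gain) {  // strict > keeps lowest (feature, threshold)
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        best.gain = gain;
        best.found = true;
      }
    }
  }
  if (best.gain <= 0.0) best.found = false;
  return best;
}

// [[Rcpp::export]]
List cpp_best_split(const NumericMatrix& X, const NumericMatrix& G,
                    const NumericMatrix& H, double lambda2, int min_child) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  Split s = scan_split(X, G, H, rows, lambda2, min_child);
  return List::create(_["found"] = s.found,
                      _["feature"] = s.feature + 1,
                      _["threshold"] = s.threshold,
                      _["gain"] = s.gain);
}

struct Node {
  int feature = -1;           // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int depth = 0;
  std::vector<int> rows;
  Split cand;
  bool scanned = false;
};

static double soft_thresh(double g, double l1) {
  if (g > l1) return g - l1;
  if (g < -l1) return g + l1;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_grow_tree(const NumericMatrix& X, const NumericMatrix& G,
                   const NumericMatrix& H, double lambda1, double lambda2,
                   int num_leaves, int max_depth, int min_child) {
  const int n = X.nrow(), T = G.ncol();
  std::vector<Node> nodes;
  Node root;
  root.rows.resize(n);
  for (int i = 0; i < n; ++i) root.rows[i] = i;
  nodes.push_back(std::move(root));
  int n_leaves = 1;
  while (n_leaves < num_leaves) {
    int best_node = -1;
    double best_gain = 0.0;
    for (size_t k = 0; k < nodes.size(); ++k) {
      Node& nd = nodes[k];
      if (nd.feature != -1) continue;          // internal
      if (nd.depth >= max_depth) continue;
      if (!nd.scanned) {
        nd.cand = scan_split(X, G, H, nd.rows, lambda2, min_child);
        nd.scanned = true;
      }
      if (nd.cand.found && nd.cand.gain > best_gain) {
        best_gain = nd.cand.gain;
        best_node = (int)k;
      }
    }
    if (best_node < 0) break;
    Node& nd = nodes[best_node];
    Node lc, rc;
    lc.depth = rc.depth = nd.depth + 1;
    for (int r : nd.rows) {
      if (X(r, nd.cand.feature) <= nd.cand.threshold) lc.rows.push_back(r);
      else rc.rows.push_back(r);
    }
    nd.feature = nd.cand.feature;
    nd.threshold = nd.cand.threshold;
    nd.left = (int)nodes.size();
    nd.right = (int)nodes.size() + 1;
    std::vector<int>().swap(nd.rows);
    nodes.push_back(std::move(lc));
    nodes.push_back(std::move(rc));
    n_leaves += 1;
  }
  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), depth(m);
  NumericVector threshold(m);
  NumericMatrix leaf_values(m, T);
  IntegerVector row_node(n);
  for (int k = 0; k < m; ++k) {
    const Node& nd = nodes[k];
    feature[k] = nd.feature >= 0 ? nd.feature + 1 : -1;
    threshold[k] = nd.threshold;
    left[k] = nd.left >= 0 ? nd.left + 1 : -1;
    right[k] = nd.right >= 0 ? nd.right + 1 : -1;
    depth[k] = nd.depth;
    if (nd.feature == -1) {
      for (int t = 0; t < T; ++t) {
        double Gs = 0.0, Hs = 0.0;
        for (int r : nd.rows) { Gs += G(r, t); Hs += H(r, t); }
        double denom = Hs + lambda2;
        leaf_values(k, t) = denom > 0 ? -soft_thresh(Gs, lambda1) / denom : 0.0;
      }
      for (int r : nd.rows) row_node[r] = k + 1;
    }
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["depth"] = depth, _["leaf_values"] = leaf_values,
                      _["row_node"] = row_node,
                      _["n_leaves"] = n_leaves);
}

// [[Rcpp::export]]
IntegerVector cpp_route(const IntegerVector& feature,
                        const NumericVector& threshold,
                        const IntegerVector& left, const IntegerVector& right,
                        const NumericMatrix& X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] != -1) {
      if (X(i, feature[k] - 1) <= threshold[k]) k = left[k] - 1;
      else k = right[k] - 1;
    }
    out[i] = k + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_ensemble(const List& trees, const NumericMatrix& X,
                                   int task, int n_trees, double lr,
                                   double base) {
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int j = 0; j < n_trees; ++j) {
    List tr = trees[j];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericMatrix lv = tr["leaf_values"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feature[k] != -1) {
        if (X(i, feature[k] - 1) <= threshold[k]) k = left[k] - 1;
        else k = right[k] - 1;
      }
      out[i] += lr * lv(k, task - 1);
    }
  }
  return out;
}
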