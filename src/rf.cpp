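// Compact classification random forest for marker ranking and CV:
// CART trees on continuous features, Gini impurity, bootstrap resampling,
// mtry features per node, grown to purity (min_node = 1 by default).
// Importance = node-size-weighted Gini decrease summed over the forest.
// Self-contained RNG (mt19937) so results are seed-deterministic and
// independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;        // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

class Tree {
public:
  std::vector<Node> nodes;

  Tree(const NumericMatrix& X, const IntegerVector& y, int mtry,
       int min_node, std::mt19937& rng, std::vector<double>* imp)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node), rng_(rng), imp_(imp) {}

  int build(std::vector<int>& idx) {
    const int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y_[i];
    Node nd;
    nd.pred = (2 * n1 > n) ? 1 : 0;
    const int me = static_cast<int>(nodes.size());
    nodes.push_back(nd);
    if (n < 2 * min_node_ || n1 == 0 || n1 == n) return me;

    const double g = gini(n1, n);
    const int p = X_.ncol();
    // partial Fisher-Yates to draw mtry distinct features
    std::vector<int> feats(p);
    std::iota(feats.begin(), feats.end(), 0);
    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> s;
    for (int k = 0; k < mtry_; ++k) {
      std::uniform_int_distribution<int> pick(k, p - 1);
      std::swap(feats[k], feats[pick(rng_)]);
      const int f = feats[k];
      s = idx;
      std::sort(s.begin(), s.end(), [&](int a, int b) {
        return X_(a, f) < X_(b, f);
      });
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += y_[s[i]];
        if (X_(s[i], f) == X_(s[i + 1], f)) continue;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node_ || nr < min_node_) continue;
        const double dec =
          g - (nl * gini(l1, nl) + nr * gini(n1 - l1, nr)) / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (X_(s[i], f) + X_(s[i + 1], f));
        }
      }
    }
    if (best_f < 0) return me;
    if (imp_) (*imp_)[best_f] += best_dec * n;
    std::vector<int> li, ri;
    for (int i : idx)
      (X_(i, best_f) <= best_thr ? li : ri).push_back(i);
    nodes[me].feat = best_f;
    nodes[me].thr = best_thr;
    const int l = build(li);
    nodes[me].left = l;
    const int r = build(ri);
    nodes[me].right = r;
    return me;
  }

  int predict(const NumericMatrix& Xnew, int row) const {
    int cur = 0;
    while (nodes[cur].feat >= 0)
      cur = (Xnew(row, nodes[cur].feat) <= nodes[cur].thr)
              ? nodes[cur].left : nodes[cur].right;
    return nodes[cur].pred;
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_;
  std::mt19937& rng_;
  std::vector<double>* imp_;
};

std::vector<int> bootstrap(int n, std::mt19937& rng) {
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = pick(rng);
  return idx;
}

}  // namespace

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y,
                                int ntree, int mtry, int min_node,
                                int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<double> imp(p, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx = bootstrap(n, rng);
    Tree tree(X, y, mtry, min_node, rng, &imp);
    tree.build(idx);
  }
  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = imp[j] / ntree;
  return out;
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest, int ntree, int mtry,
                             int min_node, int seed) {
  const int n = Xtrain.nrow(), m = Xtest.nrow();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> votes(m, 0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx = bootstrap(n, rng);
    Tree tree(Xtrain, ytrain, mtry, min_node, rng, nullptr);
    tree.build(idx);
    for (int i = 0; i < m; ++i) votes[i] += tree.predict(Xtest, i);
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = (2 * votes[i] > ntree) ? 1 : 0;
  return out;
}
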