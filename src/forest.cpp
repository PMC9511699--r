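// Compact random forest for probability estimation: bagged CART trees with
// Gini splits and a random feature subset (mtry) at every node. Leaf class
// proportions are averaged over trees. Deterministic given `seed` (own
// xorshift RNG, independent of R's RNG state).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2862933555777941757ULL + 3037000493ULL) {
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature = -1;          // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> prob;  // leaf class proportions
};

struct Tree {
  std::vector<Node> nodes;

  const std::vector<double>& predict_row(const NumericMatrix& X, int row) const {
    int id = 0;
    while (nodes[id].feature >= 0)
      id = (X(row, nodes[id].feature) <= nodes[id].threshold)
             ? nodes[id].left : nodes[id].right;
    return nodes[id].prob;
  }
};

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int K, int mtry,
          Rng& rng)
    : X_(X), y_(y), K_(K), mtry_(mtry), p_(X.ncol()), rng_(rng) {}

  Tree grow(const std::vector<int>& bootstrap) {
    tree_.nodes.clear();
    std::vector<int> idx = bootstrap;
    build(idx, 0, 25);
    return tree_;
  }

private:
  int make_leaf(const std::vector<int>& idx) {
    Node n;
    n.prob.assign(K_, 0.0);
    for (int i : idx) n.prob[y_[i]] += 1.0;
    for (double& v : n.prob) v /= idx.size();
    tree_.nodes.push_back(n);
    return static_cast<int>(tree_.nodes.size()) - 1;
  }

  // returns node id
  int build(std::vector<int>& idx, int depth, int max_depth) {
    const int n = static_cast<int>(idx.size());
    bool pure = true;
    for (int i = 1; i < n && pure; ++i) pure = (y_[idx[i]] == y_[idx[0]]);
    if (pure || n < 2 || depth >= max_depth) return make_leaf(idx);

    int best_f = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<double> total(K_, 0.0);
    for (int i : idx) total[y_[i]] += 1.0;
    double gini_all = 1.0;
    for (double c : total) gini_all -= (c / n) * (c / n);

    // sample mtry distinct features
    std::vector<int> feats(p_);
    for (int j = 0; j < p_; ++j) feats[j] = j;
    for (int j = 0; j < mtry_ && j < p_; ++j)
      std::swap(feats[j], feats[j + rng_.below(p_ - j)]);

    std::vector<int> ord(idx);
    std::vector<double> left(K_);
    for (int m = 0; m < mtry_ && m < p_; ++m) {
      const int f = feats[m];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X_(a, f) < X_(b, f);
      });
      std::fill(left.begin(), left.end(), 0.0);
      double sumsq_l = 0.0, sumsq_r = 0.0;
      for (double c : total) sumsq_r += c * c;
      for (int i = 0; i < n - 1; ++i) {
        const int cls = y_[ord[i]];
        // incremental sums of squared class counts on each side
        sumsq_l += 2.0 * left[cls] + 1.0;
        sumsq_r -= 2.0 * (total[cls] - left[cls]) - 1.0;
        left[cls] += 1.0;
        const double xv = X_(ord[i], f), xn = X_(ord[i + 1], f);
        if (xv == xn) continue;              // can't cut between equal values
        const int nl = i + 1, nr = n - nl;
        const double gini_l = 1.0 - sumsq_l / (double(nl) * nl);
        const double gini_r = 1.0 - sumsq_r / (double(nr) * nr);
        const double gain =
          gini_all - (nl * gini_l + nr * gini_r) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = xv + (xn - xv) / 2.0;
        }
      }
      // reset class totals for next feature
      for (int k = 0; k < K_; ++k) left[k] = 0.0;
    }
    if (best_f < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    for (int i : idx)
      (X_(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(idx);

    Node n2;
    n2.feature = best_f;
    n2.threshold = best_thr;
    tree_.nodes.push_back(n2);
    const int me = static_cast<int>(tree_.nodes.size()) - 1;
    const int l = build(li, depth + 1, max_depth);   // may reallocate nodes
    tree_.nodes[me].left = l;
    const int r = build(ri, depth + 1, max_depth);
    tree_.nodes[me].right = r;
    return me;
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int K_, mtry_, p_;
  Rng& rng_;
  Tree tree_;
};

} // namespace

// [[Rcpp::export]]
NumericMatrix rf_fit_predict(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest, int K, int n_trees,
                             int mtry, int seed) {
  const int n = Xtrain.nrow(), ntest = Xtest.nrow();
  if (n < 2) stop("random forest needs at least 2 training rows");
  if (Xtest.ncol() != Xtrain.ncol()) stop("feature-count mismatch");
  for (int i = 0; i < n; ++i)
    if (ytrain[i] < 0 || ytrain[i] >= K) stop("class label out of range");
  Rng rng(static_cast<uint64_t>(seed));
  Builder builder(Xtrain, ytrain, K, mtry, rng);
  NumericMatrix out(ntest, K);
  std::vector<int> boot(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    Tree tree = builder.grow(boot);
    for (int r = 0; r < ntest; ++r) {
      const std::vector<double>& pr = tree.predict_row(Xtest, r);
      for (int k = 0; k < K; ++k) out(r, k) += pr[k];
    }
  }
  for (int r = 0; r < ntest; ++r)
    for (int k = 0; k < K; ++k) out(r, k) /= n_trees;
  return out;
}
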