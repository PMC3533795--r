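#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Compact depth-bounded random forest for binary labels.
//
// The descriptor-subset search evaluates tens of thousands of tiny forests
// (n ~ 300 rows, 1-4 columns, 5 trees), so the fit must cost microseconds,
// be a pure function of (data, parameters, seed), and break majority-vote
// ties toward the positive ("active") class. Trees are CART-style with Gini
// impurity, one bootstrap resample of the rows per tree, and `mtry` features
// drawn uniformly at each split.

namespace {

// xorshift64* generator: deterministic, independent of R's RNG state.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    // scramble small seeds apart
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feat;     // -1 for leaf
  double thr;   // go left when x <= thr
  int left, right;
  int pred;     // leaf prediction (0/1); majority with ties -> 1
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, maxdepth;
  Rng& rng;
  std::vector<Node> nodes;
  std::vector<int> idx;  // row indices of the bootstrap sample, partitioned in place
  std::vector<int> featpool;
  std::vector<std::pair<double, int>> vals;  // split-scan buffer, reused

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_, int maxdepth_,
          Rng& rng_)
      : X(X_), y(y_), mtry(mtry_), maxdepth(maxdepth_), rng(rng_) {
    featpool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) featpool[j] = j;
    vals.reserve(X.nrow());
  }

  int leaf(int n1, int n) {
    Node nd;
    nd.feat = -1;
    nd.thr = 0.0;
    nd.left = nd.right = -1;
    nd.pred = (2 * n1 >= n) ? 1 : 0;  // tie -> active
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  int build(int lo, int hi, int depth) {
    const int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
    if (depth >= maxdepth || n < 2 || n1 == 0 || n1 == n) return leaf(n1, n);

    const double parent = static_cast<double>(n1) * (n - n1) / n;
    double best = parent;
    int bestf = -1;
    double bestthr = 0.0;

    // draw mtry distinct features (partial Fisher-Yates)
    const int p = static_cast<int>(featpool.size());
    const int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      const int r = k + rng.below(p - k);
      std::swap(featpool[k], featpool[r]);
    }

    vals.resize(n);
    for (int k = 0; k < m; ++k) {
      const int f = featpool[k];
      for (int i = 0; i < n; ++i) {
        const int row = idx[lo + i];
        vals[i] = std::make_pair(X(row, f), y[row]);
      }
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const int r1 = n1 - l1;
        const double score = static_cast<double>(l1) * (nl - l1) / nl +
                             static_cast<double>(r1) * (nr - r1) / nr;
        if (score < best - 1e-12) {
          best = score;
          bestf = f;
          bestthr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (bestf < 0) return leaf(n1, n);

    // partition idx in place: left = x <= thr
    int i = lo, j = hi - 1;
    while (i <= j) {
      if (X(idx[i], bestf) <= bestthr) {
        ++i;
      } else {
        std::swap(idx[i], idx[j]);
        --j;
      }
    }
    const int mid = i;
    if (mid == lo || mid == hi) return leaf(n1, n);  // numeric degeneracy guard

    const int self = static_cast<int>(nodes.size());
    nodes.push_back(Node());  // placeholder; children appended after
    const int L = build(lo, mid, depth + 1);
    const int R = build(mid, hi, depth + 1);
    nodes[self].feat = bestf;
    nodes[self].thr = bestthr;
    nodes[self].left = L;
    nodes[self].right = R;
    nodes[self].pred = (2 * n1 >= n) ? 1 : 0;
    return self;
  }
};

int treePredict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    const int f = static_cast<int>(tree(node, 0));
    if (f < 0) return static_cast<int>(tree(node, 4));
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
  }
}

}  // namespace

// [[Rcpp::export(name = ".rf_train")]]
List rf_train(NumericMatrix X, IntegerVector y, int ntrees, int maxdepth, int mtry,
              double seed) {
  const int n = X.nrow();
  if (n == 0) stop("no rows to train on");
  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  List forest(ntrees);
  for (int t = 0; t < ntrees; ++t) {
    Builder b(X, y, mtry, maxdepth, rng);
    b.idx.resize(n);
    for (int i = 0; i < n; ++i) b.idx[i] = rng.below(n);  // bootstrap resample
    const int root = b.build(0, n, 0);
    (void)root;  // root is always node 0
    const int nn = static_cast<int>(b.nodes.size());
    NumericMatrix tm(nn, 5);
    for (int k = 0; k < nn; ++k) {
      tm(k, 0) = b.nodes[k].feat;
      tm(k, 1) = b.nodes[k].thr;
      tm(k, 2) = b.nodes[k].left;
      tm(k, 3) = b.nodes[k].right;
      tm(k, 4) = b.nodes[k].pred;
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
IntegerVector rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int T = forest.size();
  IntegerVector out(n);
  std::vector<NumericMatrix> trees;
  trees.reserve(T);
  for (int t = 0; t < T; ++t) trees.push_back(as<NumericMatrix>(forest[t]));
  for (int i = 0; i < n; ++i) {
    int v1 = 0;
    for (int t = 0; t < T; ++t) v1 += treePredict(trees[t], X, i);
    out[i] = (2 * v1 >= T) ? 1 : 0;  // vote tie -> active
  }
  return out;
}
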