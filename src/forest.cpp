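// Classification random forest: bootstrap aggregation of CART trees grown
// with Gini impurity and a random feature subset (mtry) at every split.
// Self-contained (own mt19937 stream) so fits are bit-reproducible from a
// single integer seed, independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;   // -1 for leaf
  double thresh; // go left if x <= thresh
  int left, right;
  int pred;      // majority class at the node (valid for leaves)
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int nclass, mtry, min_split;
  std::mt19937 &rng;
  std::vector<Node> nodes;
  std::vector<double> &importance; // accumulated weighted impurity decrease
  int n_total;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int nclass_,
              int mtry_, int min_split_, std::mt19937 &rng_,
              std::vector<double> &imp_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), min_split(min_split_),
        rng(rng_), importance(imp_), n_total(X_.nrow()) {}

  static double gini(const std::vector<int> &counts, int n) {
    if (n == 0) return 0.0;
    double s = 0.0;
    for (int c : counts) { double p = (double)c / n; s += p * p; }
    return 1.0 - s;
  }

  int majority(const std::vector<int> &counts) {
    int best = 0;
    for (size_t c = 1; c < counts.size(); ++c)
      if (counts[c] > counts[best]) best = (int)c; // tie -> lowest class
    return best;
  }

  // Build a node from sample index set; returns node id.
  int build(std::vector<int> &idx) {
    int n = (int)idx.size();
    std::vector<int> counts(nclass, 0);
    for (int i : idx) counts[y[i]]++;
    int pred = majority(counts);
    double imp = gini(counts, n);

    int id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    if (n < min_split || imp <= 0.0) return id;

    // sample mtry distinct features (partial Fisher-Yates)
    int p = X.ncol();
    int m = std::min(mtry, p);
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> u(j, p - 1);
      std::swap(feats[j], feats[u(rng)]);
    }

    double best_dec = 0.0, best_thresh = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> lc(nclass);
    for (int fj = 0; fj < m; ++fj) {
      int f = feats[fj];
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), y[idx[k]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      for (int k = 0; k < n - 1; ++k) {
        lc[vals[k].second]++; nl++;
        if (vals[k].first == vals[k + 1].first) continue;
        int nr = n - nl;
        std::vector<int> rc(nclass);
        for (int c = 0; c < nclass; ++c) rc[c] = counts[c] - lc[c];
        double dec = imp - ((double)nl / n) * gini(lc, nl)
                         - ((double)nr / n) * gini(rc, nr);
        if (dec > best_dec + 1e-15) {
          best_dec = dec;
          best_feat = f;
          best_thresh = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return id;

    importance[best_feat] += best_dec * ((double)n / n_total);
    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx)
      (X(i, best_feat) <= best_thresh ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return id; // numerically degenerate split
    nodes[id].feature = best_feat;
    nodes[id].thresh = best_thresh;
    int l = build(li);
    int r = build(ri);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

NumericMatrix pack(const std::vector<Node> &nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].thresh;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].pred;
  }
  return m;
}

int predict_one(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return (int)tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_split, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, nclass, mtry, min_split, rng, importance);
    tb.build(idx);
    trees[t] = pack(tb.nodes);
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j)
    imp[j] = (tot > 0.0) ? importance[j] / tot : 1.0 / p;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["nclass"] = nclass);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int nclass = as<int>(forest["nclass"]);
  int n = X.nrow(), ntree = trees.size();
  IntegerVector out(n);
  std::vector<int> votes(nclass);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < ntree; ++t) {
      NumericMatrix tree = trees[t];
      votes[predict_one(tree, X, i)]++;
    }
    int best = 0;
    for (int c = 1; c < nclass; ++c)
      if (votes[c] > votes[best]) best = c; // tie -> lowest class
    out[i] = best;
  }
  return out;
}
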