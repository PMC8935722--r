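// Probability-estimation random forest for {0,1,2}-coded SNP features.
//
// Trees split on the two ordered genotype cut points ({0} vs {1,2} and
// {0,1} vs {2}), minimizing weighted child Gini impurity i(t) = 2 p (1-p).
// Leaves hold the in-bag empirical class-1 fraction; the forest prediction
// is the arithmetic mean of the tree leaf probabilities. Out-of-bag indices
// are recorded per tree for the permutation variable importance.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <set>
using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; feature = -1 marks a leaf
  std::vector<int> feature, cut, left, right;
  std::vector<double> prob;

  int new_node() {
    feature.push_back(-1); cut.push_back(-1);
    left.push_back(-1); right.push_back(-1); prob.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

// mtry distinct feature indices, uniform without replacement, ascending
// so that ties break on the lowest feature index.
std::vector<int> draw_candidates(int p, int mtry, std::mt19937_64 &rng) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  for (int i = 0; i < mtry; ++i) {
    std::uniform_int_distribution<int> d(i, p - 1);
    std::swap(pool[i], pool[d(rng)]);
  }
  pool.resize(mtry);
  std::sort(pool.begin(), pool.end());
  return pool;
}

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double q = n1 / n;
  return 2.0 * q * (1.0 - q);
}

void grow_node(Tree &tree, int node, std::vector<int> &samples,
               const IntegerMatrix &X, const IntegerVector &y,
               int mtry, int min_node_size, std::mt19937_64 &rng) {
  const int n = (int)samples.size();
  int n1 = 0;
  for (int i : samples) n1 += y[i];
  tree.prob[node] = (double)n1 / n;

  if (n < 2 * min_node_size || n1 == 0 || n1 == n) return;

  const double parent_imp = gini(n1, n);
  int best_feature = -1, best_cut = -1;
  double best_imp = parent_imp - 1e-12;

  std::vector<int> cand = draw_candidates(X.ncol(), mtry, rng);
  for (int j : cand) {
    int cnt[3] = {0, 0, 0}, cnt1[3] = {0, 0, 0};
    for (int i : samples) {
      int g = X(i, j);
      ++cnt[g];
      cnt1[g] += y[i];
    }
    for (int c = 0; c <= 1; ++c) {  // left: genotype <= c
      int nL = cnt[0] + (c == 1 ? cnt[1] : 0);
      int nR = n - nL;
      if (nL < min_node_size || nR < min_node_size) continue;
      int n1L = cnt1[0] + (c == 1 ? cnt1[1] : 0);
      int n1R = n1 - n1L;
      double imp = (nL * gini(n1L, nL) + nR * gini(n1R, nR)) / n;
      if (imp < best_imp) {
        best_imp = imp;
        best_feature = j;
        best_cut = c;
      }
    }
  }
  if (best_feature < 0) return;

  std::vector<int> ls, rs;
  for (int i : samples) {
    if (X(i, best_feature) <= best_cut) ls.push_back(i); else rs.push_back(i);
  }
  tree.feature[node] = best_feature;
  tree.cut[node] = best_cut;
  int l = tree.new_node(), r = tree.new_node();
  tree.left[node] = l;
  tree.right[node] = r;
  grow_node(tree, l, ls, X, y, mtry, min_node_size, rng);
  grow_node(tree, r, rs, X, y, mtry, min_node_size, rng);
}

// flat view of a stored tree, extracted once per tree
struct TreeView {
  IntegerVector feature, cut, left, right;
  NumericVector prob;
  explicit TreeView(const List &tr)
      : feature(tr["feature"]), cut(tr["cut"]), left(tr["left"]),
        right(tr["right"]), prob(tr["prob"]) {}
};

double predict_tree(const TreeView &tr, const IntegerMatrix &X, int row,
                    const std::vector<int> *perm, int perm_feature) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int j = tr.feature[node];
    int r = (perm && j == perm_feature) ? (*perm)[row] : row;
    node = (X(r, j) <= tr.cut[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.prob[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_forest(IntegerMatrix X, IntegerVector y, int num_trees,
                    int mtry, int min_node_size, double seed) {
  const int n = X.nrow();
  List trees(num_trees), oob_list(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + (uint64_t)t);
    std::vector<int> inbag(n);
    std::vector<char> seen(n, 0);
    std::uniform_int_distribution<int> d(0, n - 1);
    for (int i = 0; i < n; ++i) {
      int k = d(rng);
      inbag[i] = k;
      seen[k] = 1;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!seen[i]) oob.push_back(i);

    Tree tree;
    int root = tree.new_node();
    grow_node(tree, root, inbag, X, y, mtry, min_node_size, rng);

    trees[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["cut"] = IntegerVector(tree.cut.begin(), tree.cut.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["prob"] = NumericVector(tree.prob.begin(), tree.prob.end()));
    oob_list[t] = IntegerVector(oob.begin(), oob.end());  // 0-based
  }
  return List::create(_["trees"] = trees, _["oob"] = oob_list);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, IntegerMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    TreeView tr((List)trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tr, X, i, nullptr, -1);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Permutation importance: per tree, the increase in out-of-bag
// misclassification (threshold 0.5) when a feature's values are permuted
// among that tree's OOB samples, averaged over trees with OOB data.
// Features a tree never splits on contribute exactly zero for that tree.
// [[Rcpp::export]]
NumericVector cpp_permutation_vim(List trees, List oob_list, IntegerMatrix X,
                                  IntegerVector y, double seed) {
  const int p = X.ncol(), T = trees.size();
  NumericVector vim(p);
  int used_trees = 0;
  for (int t = 0; t < T; ++t) {
    IntegerVector oob = oob_list[t];
    const int m = oob.size();
    if (m == 0) continue;
    ++used_trees;
    TreeView tr((List)trees[t]);
    std::set<int> used;
    for (int k = 0; k < tr.feature.size(); ++k)
      if (tr.feature[k] >= 0) used.insert(tr.feature[k]);

    double err0 = 0.0;
    for (int k = 0; k < m; ++k) {
      int cls = predict_tree(tr, X, oob[k], nullptr, -1) > 0.5 ? 1 : 0;
      err0 += (cls != y[oob[k]]);
    }
    err0 /= m;

    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 7919ULL * (uint64_t)t);
    for (int j : used) {
      // permutation of the OOB rows, stored as a full-row lookup
      std::vector<int> shuffled(oob.begin(), oob.end());
      for (int k = m - 1; k > 0; --k) {
        std::uniform_int_distribution<int> d(0, k);
        std::swap(shuffled[k], shuffled[d(rng)]);
      }
      std::vector<int> perm(X.nrow());
      for (int i = 0; i < X.nrow(); ++i) perm[i] = i;
      for (int k = 0; k < m; ++k) perm[oob[k]] = shuffled[k];

      double err = 0.0;
      for (int k = 0; k < m; ++k) {
        int cls = predict_tree(tr, X, oob[k], &perm, j) > 0.5 ? 1 : 0;
        err += (cls != y[oob[k]]);
      }
      err /= m;
      vim[j] += err - err0;
    }
  }
  if (used_trees > 0) for (int j = 0; j < p; ++j) vim[j] /= used_trees;
  return vim;
}
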