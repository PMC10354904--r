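#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART forest grown by exhaustive Gini minimisation over a random feature
// subset at every node.  Split thresholds are midpoints between consecutive
// distinct sorted values; samples with value < threshold go left.  Ties in
// the split criterion are broken by (lowest feature index, lowest threshold)
// so trees are reproducible for a given RNG state.  All randomness (bootstrap
// resampling, per-node feature subsampling) draws from R's RNG, so set.seed()
// in R fully determines a forest.

namespace {

struct Node {
  int feature;      // 0-based split feature, -1 for leaf
  double threshold;
  int left, right;  // 0-based node ids, -1 for leaf
  int depth;
  int n;            // samples reaching the node (bootstrap multiplicity counted)
  double gini;
  std::vector<int> counts;
};

double giniFromCounts(const std::vector<int> &counts, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    double p = static_cast<double>(counts[i]) / n;
    s += p * p;
  }
  return 1.0 - s;
}

int sampleInt(int n) {  // uniform on 0..n-1 via R's RNG
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct TreeBuilder {
  const NumericMatrix &x;
  const IntegerVector &y;
  int nClasses, maxDepth, mtry, minNode;
  bool removeUsed;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix &x_, const IntegerVector &y_, int nClasses_,
              int maxDepth_, int mtry_, bool removeUsed_)
      : x(x_), y(y_), nClasses(nClasses_), maxDepth(maxDepth_), mtry(mtry_),
        minNode(2), removeUsed(removeUsed_) {}

  // returns node id
  int build(std::vector<int> &idx, int depth, std::vector<int> &allowed) {
    Node nd;
    nd.feature = -1;
    nd.threshold = NA_REAL;
    nd.left = nd.right = -1;
    nd.depth = depth;
    nd.n = static_cast<int>(idx.size());
    nd.counts.assign(nClasses, 0);
    for (size_t i = 0; i < idx.size(); ++i) nd.counts[y[idx[i]]]++;
    nd.gini = giniFromCounts(nd.counts, nd.n);

    int id = static_cast<int>(nodes.size());
    nodes.push_back(nd);

    bool pure = false;
    for (int c = 0; c < nClasses; ++c)
      if (nodes[id].counts[c] == nodes[id].n) pure = true;
    if (depth >= maxDepth || nodes[id].n < minNode || pure ||
        allowed.empty())
      return id;

    // draw min(mtry, |allowed|) candidate features without replacement
    int nAllowed = static_cast<int>(allowed.size());
    int nCand = std::min(mtry, nAllowed);
    std::vector<int> pool(allowed);
    for (int i = 0; i < nCand; ++i) {
      int j = i + sampleInt(nAllowed - i);
      std::swap(pool[i], pool[j]);
    }

    // best split over candidates
    double bestGini = R_PosInf;
    int bestFeat = -1;
    double bestThr = 0.0;
    const double eps = 1e-12;
    int n = nodes[id].n;

    std::vector<std::pair<double, int> > vals(n);  // (value, class)
    std::vector<int> leftCounts(nClasses);

    for (int ci = 0; ci < nCand; ++ci) {
      int f = pool[ci];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(x(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;  // constant feature
      std::fill(leftCounts.begin(), leftCounts.end(), 0);
      for (int i = 1; i < n; ++i) {
        leftCounts[vals[i - 1].second]++;
        if (vals[i].first <= vals[i - 1].first) continue;
        double thr = 0.5 * (vals[i - 1].first + vals[i].first);
        // left = first i samples (value < thr)
        double sl = 0.0, sr = 0.0;
        for (int c = 0; c < nClasses; ++c) {
          double pl = static_cast<double>(leftCounts[c]) / i;
          double pr =
              static_cast<double>(nodes[id].counts[c] - leftCounts[c]) /
              (n - i);
          sl += pl * pl;
          sr += pr * pr;
        }
        double g = (i * (1.0 - sl) + (n - i) * (1.0 - sr)) / n;
        bool better = g < bestGini - eps;
        bool tie = !better && g < bestGini + eps && bestFeat >= 0;
        if (better || (tie && (f < bestFeat ||
                               (f == bestFeat && thr < bestThr)))) {
          bestGini = g;
          bestFeat = f;
          bestThr = thr;
        }
      }
    }

    if (bestFeat < 0) return id;  // all candidates constant -> leaf

    std::vector<int> leftIdx, rightIdx;
    leftIdx.reserve(n);
    rightIdx.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (x(idx[i], bestFeat) < bestThr)
        leftIdx.push_back(idx[i]);
      else
        rightIdx.push_back(idx[i]);
    }
    if (leftIdx.empty() || rightIdx.empty()) return id;  // defensive

    std::vector<int> childAllowed;
    std::vector<int> *allowedPtr = &allowed;
    if (removeUsed) {
      childAllowed.reserve(allowed.size());
      for (size_t i = 0; i < allowed.size(); ++i)
        if (allowed[i] != bestFeat) childAllowed.push_back(allowed[i]);
      allowedPtr = &childAllowed;
    }

    nodes[id].feature = bestFeat;
    nodes[id].threshold = bestThr;
    int lid = build(leftIdx, depth + 1, *allowedPtr);
    nodes[id].left = lid;
    int rid = build(rightIdx, depth + 1, *allowedPtr);
    nodes[id].right = rid;
    return id;
  }
};

}  // namespace

// [[Rcpp::export]]
List cppTrainForest(NumericMatrix x, IntegerVector y, int nClasses,
                    int nTrees, int maxDepth, int mtry, bool bootstrap,
                    bool removeUsed) {
  int m = x.nrow();
  List trees(nTrees);
  for (int t = 0; t < nTrees; ++t) {
    std::vector<int> idx(m);
    IntegerVector boot(m);
    if (bootstrap) {
      for (int i = 0; i < m; ++i) {
        idx[i] = sampleInt(m);
        boot[i] = idx[i] + 1;
      }
    } else {
      for (int i = 0; i < m; ++i) {
        idx[i] = i;
        boot[i] = i + 1;
      }
    }
    std::vector<int> allowed(x.ncol());
    for (int f = 0; f < static_cast<int>(allowed.size()); ++f) allowed[f] = f;

    TreeBuilder tb(x, y, nClasses, maxDepth, mtry, removeUsed);
    tb.build(idx, 0, allowed);

    int nn = static_cast<int>(tb.nodes.size());
    NumericMatrix nodeMat(nn, 7);
    IntegerMatrix countMat(nn, nClasses);
    for (int i = 0; i < nn; ++i) {
      const Node &nd = tb.nodes[i];
      nodeMat(i, 0) = nd.feature < 0 ? NA_REAL : nd.feature + 1.0;
      nodeMat(i, 1) = nd.threshold;
      nodeMat(i, 2) = nd.left < 0 ? NA_REAL : nd.left + 1.0;
      nodeMat(i, 3) = nd.right < 0 ? NA_REAL : nd.right + 1.0;
      nodeMat(i, 4) = nd.depth;
      nodeMat(i, 5) = nd.n;
      nodeMat(i, 6) = nd.gini;
      for (int c = 0; c < nClasses; ++c) countMat(i, c) = nd.counts[c];
    }
    colnames(nodeMat) = CharacterVector::create(
        "feature", "threshold", "left", "right", "depth", "n", "gini");
    trees[t] = List::create(Named("nodes") = nodeMat,
                            Named("counts") = countMat,
                            Named("bootstrap") = boot);
  }
  return trees;
}

// [[Rcpp::export]]
IntegerMatrix cppPredictForest(List trees, NumericMatrix x) {
  // per-sample votes: trees x samples matrix of 1-based class predictions
  int m = x.nrow();
  int nt = trees.size();
  IntegerMatrix votes(nt, m);
  for (int t = 0; t < nt; ++t) {
    List tree = trees[t];
    NumericMatrix nodes = tree["nodes"];
    IntegerMatrix counts = tree["counts"];
    int nClasses = counts.ncol();
    for (int i = 0; i < m; ++i) {
      int node = 0;
      while (!NumericVector::is_na(nodes(node, 0))) {
        int f = static_cast<int>(nodes(node, 0)) - 1;
        node = x(i, f) < nodes(node, 1)
                   ? static_cast<int>(nodes(node, 2)) - 1
                   : static_cast<int>(nodes(node, 3)) - 1;
      }
      int best = 0;
      for (int c = 1; c < nClasses; ++c)
        if (counts(node, c) > counts(node, best)) best = c;
      votes(t, i) = best + 1;
    }
  }
  return votes;
}
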