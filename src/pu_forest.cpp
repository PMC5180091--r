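// Positive-unlabeled random forest: stratified down-sampled bootstraps,
// CART/Gini trees, exact per-tree in-bag bookkeeping and out-of-bag
// soft-vote posteriors. Trees use a counter-based per-tree RNG so tree t is
// reproducible from (master seed, t) alone, independent of fitting order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {  // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) {  // Lemire multiply-shift; n < 2^31
    return static_cast<int>((static_cast<__uint128_t>(next()) *
                             static_cast<__uint128_t>(n)) >> 64);
  }
};

inline uint64_t treeSeed(uint64_t master, uint64_t t) {
  // distinct, well-mixed stream per (seed, tree index)
  return master * 0x9E3779B97F4A7C15ULL + t * 0xD1B54A32D192ED03ULL + 1ULL;
}

const int NCLASS = 3;

struct Tree {
  std::vector<int> feature;       // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> counts;     // NCLASS per node (leaf class counts)
};

inline double gini(const double* c, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (int k = 0; k < NCLASS; ++k) s += c[k] * c[k];
  return 1.0 - s / (n * n);
}

void sampleBag(Rng& rng, const std::vector<int>& pool, int draw, bool replace,
               std::vector<int>& out) {
  int n = pool.size();
  if (replace || draw > n) {
    for (int i = 0; i < draw; ++i) out.push_back(pool[rng.below(n)]);
  } else {
    std::vector<int> perm(pool);
    for (int i = 0; i < draw; ++i) {
      int j = i + rng.below(n - i);
      std::swap(perm[i], perm[j]);
      out.push_back(perm[i]);
    }
  }
}

struct Builder {
  const NumericMatrix& X;      // training rows only
  const IntegerVector& y;      // 0..2 per training row
  int mtry, minNodeSize, maxDepth;
  Rng& rng;
  Tree tree;
  std::vector<double>& importance;  // per feature, accumulated
  int bagSize;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int minNode_, int maxDepth_, Rng& rng_, std::vector<double>& imp_,
          int bagSize_)
      : X(X_), y(y_), mtry(mtry_), minNodeSize(minNode_), maxDepth(maxDepth_),
        rng(rng_), importance(imp_), bagSize(bagSize_) {}

  int makeLeaf(const double* cnt) {
    int id = tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    for (int k = 0; k < NCLASS; ++k) tree.counts.push_back(cnt[k]);
    return id;
  }

  int build(std::vector<int>& rows, int depth) {
    double cnt[NCLASS] = {0, 0, 0};
    for (int r : rows) cnt[y[r]] += 1.0;
    double n = rows.size();
    double impP = gini(cnt, n);
    bool pure = impP <= 0.0;
    if (pure || (int)rows.size() <= minNodeSize ||
        (maxDepth > 0 && depth >= maxDepth))
      return makeLeaf(cnt);

    int p = X.ncol();
    // sample mtry features without replacement, then scan in index order so
    // Gini ties resolve to the lowest feature index
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int i = 0; i < m; ++i) {
      int j = i + rng.below(p - i);
      std::swap(feats[i], feats[j]);
    }
    feats.resize(m);
    std::sort(feats.begin(), feats.end());

    int bestF = -1;
    double bestThr = 0.0, bestDec = 1e-12;
    std::vector<std::pair<double, int>> vals;
    vals.reserve(rows.size());
    for (int f : feats) {
      vals.clear();
      for (int r : rows) vals.push_back({X(r, f), y[r]});
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double cl[NCLASS] = {0, 0, 0};
      double cr[NCLASS] = {cnt[0], cnt[1], cnt[2]};
      size_t i = 0;
      while (i < vals.size()) {
        // move the whole block of equal values to the left side
        double v = vals[i].first;
        while (i < vals.size() && vals[i].first == v) {
          cl[vals[i].second] += 1.0;
          cr[vals[i].second] -= 1.0;
          ++i;
        }
        if (i == vals.size()) break;
        double nl = i, nr = n - i;
        double dec = impP - (nl / n) * gini(cl, nl) - (nr / n) * gini(cr, nr);
        if (dec > bestDec) {
          bestDec = dec;
          bestF = f;
          bestThr = (v + vals[i].first) / 2.0;
        }
      }
    }
    if (bestF < 0) return makeLeaf(cnt);

    importance[bestF] += (n / bagSize) * bestDec;

    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, bestF) <= bestThr) lrows.push_back(r);
      else rrows.push_back(r);
    }
    int id = tree.feature.size();
    tree.feature.push_back(bestF);
    tree.threshold.push_back(bestThr);
    tree.left.push_back(-2);
    tree.right.push_back(-2);
    for (int k = 0; k < NCLASS; ++k) tree.counts.push_back(cnt[k]);
    int l = build(lrows, depth + 1);
    int r = build(rrows, depth + 1);
    tree.left[id] = l;
    tree.right[id] = r;
    return id;
  }
};

List treeToList(const Tree& t, const std::vector<int>& bag) {
  int nn = t.feature.size();
  NumericMatrix counts(nn, NCLASS);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < NCLASS; ++k) counts(i, k) = t.counts[i * NCLASS + k];
  IntegerVector bagR(bag.begin(), bag.end());
  for (int i = 0; i < bagR.size(); ++i) bagR[i] += 1;  // 1-based for R
  return List::create(_["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
                      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["counts"] = counts,
                      _["in_bag"] = bagR);
}

}  // namespace

// [[Rcpp::export(name = ".cppSampleBag")]]
List cppSampleBag(IntegerVector posIdx, IntegerVector bgIdx, int positiveDraw,
                  int bgDraw, bool replacePositives, double seed,
                  int treeIndex) {
  Rng rng(treeSeed(static_cast<uint64_t>(seed),
                   static_cast<uint64_t>(treeIndex)));
  std::vector<int> pos(posIdx.begin(), posIdx.end());
  std::vector<int> bg(bgIdx.begin(), bgIdx.end());
  for (auto& v : pos) --v;
  for (auto& v : bg) --v;
  std::vector<int> bag;
  sampleBag(rng, pos, positiveDraw, replacePositives, bag);
  sampleBag(rng, bg, bgDraw, true, bag);
  IntegerVector out(bag.begin(), bag.end());
  for (int i = 0; i < out.size(); ++i) out[i] += 1;
  return List::create(_["bag"] = out);
}

// [[Rcpp::export(name = ".cppFitForest")]]
List cppFitForest(NumericMatrix X, IntegerVector y, IntegerVector posIdx,
                  IntegerVector bgIdx, int nTrees, int mtry, int minNodeSize,
                  int maxDepth, double seed, int positiveDraw, int bgDraw,
                  bool replacePositives) {
  std::vector<int> pos(posIdx.begin(), posIdx.end());
  std::vector<int> bg(bgIdx.begin(), bgIdx.end());
  for (auto& v : pos) --v;
  for (auto& v : bg) --v;
  if (pos.empty() || bg.empty()) stop("empty stratum");

  List trees(nTrees);
  std::vector<double> importance(X.ncol(), 0.0);
  for (int t = 0; t < nTrees; ++t) {
    Rng rng(treeSeed(static_cast<uint64_t>(seed),
                     static_cast<uint64_t>(t + 1)));
    std::vector<int> bag;
    sampleBag(rng, pos, positiveDraw, replacePositives, bag);
    sampleBag(rng, bg, bgDraw, true, bag);
    Builder b(X, y, mtry, minNodeSize, maxDepth, rng, importance, bag.size());
    std::vector<int> rows(bag);
    b.build(rows, 0);
    trees[t] = treeToList(b.tree, bag);
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".cppOobPosteriors")]]
List cppOobPosteriors(List trees, NumericMatrix Xall, IntegerVector trainRow) {
  // trainRow: for each universe gene, its 1-based index into the training
  // gene vector (the space in_bag refers to), or 0 when never trainable
  int nGenes = Xall.nrow();
  int nTrees = trees.size();
  int nTrain = 0;
  for (int g = 0; g < nGenes; ++g) nTrain = std::max(nTrain, trainRow[g]);

  NumericMatrix post(nGenes, NCLASS);
  IntegerVector nOob(nGenes);
  std::vector<char> inBagFlag(nTrain + 1, 0);

  for (int t = 0; t < nTrees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericMatrix counts = tr["counts"];
    IntegerVector bag = tr["in_bag"];

    std::fill(inBagFlag.begin(), inBagFlag.end(), 0);
    for (int i = 0; i < bag.size(); ++i) inBagFlag[bag[i]] = 1;

    for (int g = 0; g < nGenes; ++g) {
      if (trainRow[g] > 0 && inBagFlag[trainRow[g]]) continue;
      int node = 0;
      while (feature[node] >= 0) {
        node = (Xall(g, feature[node]) <= threshold[node]) ? left[node]
                                                           : right[node];
      }
      double tot = counts(node, 0) + counts(node, 1) + counts(node, 2);
      for (int k = 0; k < NCLASS; ++k) post(g, k) += counts(node, k) / tot;
      nOob[g] += 1;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  for (int g = 0; g < nGenes; ++g)
    if (nOob[g] > 0)
      for (int k = 0; k < NCLASS; ++k) post(g, k) /= nOob[g];
  return List::create(_["posterior"] = post, _["n_oob"] = nOob);
}
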