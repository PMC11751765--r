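// Regression random forest with out-of-bag skill and exact path-dependent
// TreeSHAP decomposition.  CART trees, bootstrap sampling, a random feature
// subset at every split (mtry), variance-reduction split criterion.  The
// generator is a private 64-bit LCG/xorshift stream so that fits are
// bit-reproducible across platforms for a given seed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {  // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // deterministic draw in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;       // -1 at leaves
  std::vector<double> threshold;
  std::vector<int> left, right;   // -1 at leaves
  std::vector<double> value;      // node mean of bootstrap targets
  std::vector<double> cover;      // bootstrap sample count reaching node
  int max_depth = 0;
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int p, mtry, min_leaf;
  Rng& rng;
  Tree tree;
  std::vector<int> idx;                          // bootstrap row indices
  std::vector<int> pool;                         // feature pool for sampling
  std::vector<std::pair<double, double> > vals;  // (x, y) scratch for sorting

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int min_leaf_, Rng& rng_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_leaf(min_leaf_),
        rng(rng_), pool(p) {
    for (int j = 0; j < p; ++j) pool[j] = j;
  }

  int make_node(int lo, int hi, int depth) {
    const int n = hi - lo;
    double sum = 0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    const double mean = sum / n;

    const int node = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(mean);
    tree.cover.push_back(static_cast<double>(n));
    if (depth > tree.max_depth) tree.max_depth = depth;
    if (n < 2 * min_leaf) return node;

    // draw mtry distinct candidate features (partial Fisher-Yates)
    for (int k = 0; k < mtry; ++k) {
      const int j = k + rng.below(p - k);
      std::swap(pool[k], pool[j]);
    }

    int best_f = -1;
    double best_thr = 0, best_score = -1;
    if (static_cast<int>(vals.size()) < n) vals.resize(n);
    for (int k = 0; k < mtry; ++k) {
      const int f = pool[k];
      for (int i = 0; i < n; ++i) {
        const int r = idx[lo + i];
        vals[i] = std::make_pair(X(r, f), y[r]);
      }
      std::sort(vals.begin(), vals.begin() + n);
      double sl = 0;
      for (int i = 0; i < n - 1; ++i) {
        sl += vals[i].second;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (vals[i].first >= vals[i + 1].first) continue;  // tied x: no cut here
        const double sr = sum - sl;
        const double score = sl * sl / nl + sr * sr / nr;  // maximizes SSE drop
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;  // all candidates constant within the node

    const int mid = static_cast<int>(
        std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                              [&](int r) { return X(r, best_f) <= best_thr; }) -
        idx.begin());
    if (mid == lo || mid == hi) return node;  // numeric guard, should not occur

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    const int l = make_node(lo, mid, depth + 1);
    const int r = make_node(mid, hi, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double predict_tree(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(
      _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
      _["value"] = NumericVector(t.value.begin(), t.value.end()),
      _["cover"] = NumericVector(t.cover.begin(), t.cover.end()),
      _["max_depth"] = t.max_depth);
}

Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"];
  NumericVector th = l["threshold"], v = l["value"], c = l["cover"];
  t.feature.assign(f.begin(), f.end());
  t.left.assign(le.begin(), le.end());
  t.right.assign(ri.begin(), ri.end());
  t.threshold.assign(th.begin(), th.end());
  t.value.assign(v.begin(), v.end());
  t.cover.assign(c.begin(), c.end());
  t.max_depth = as<int>(l["max_depth"]);
  return t;
}

// ---- TreeSHAP (path-dependent conditional expectations) -------------------

struct PathElement {
  int feature_index;
  double zero_fraction, one_fraction, pweight;
};

void extend_path(PathElement* path, unsigned depth, double zero_fraction,
                 double one_fraction, int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0) ? 1.0 : 0.0;
  for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / static_cast<double>(depth + 1);
    path[i].pweight =
        zero_fraction * path[i].pweight * (depth - i) / static_cast<double>(depth + 1);
  }
}

void unwind_path(PathElement* path, unsigned depth, unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  if (one_fraction != 0) {
    for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
      const double tmp = path[i].pweight;
      path[i].pweight =
          next_one_portion * (depth + 1) / ((i + 1) * one_fraction);
      next_one_portion =
          tmp - path[i].pweight * zero_fraction * (depth - i) /
                    static_cast<double>(depth + 1);
    }
  } else {
    for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
      path[i].pweight = path[i].pweight * (depth + 1) /
                        (zero_fraction * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement* path, unsigned depth,
                        unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0;
  if (one_fraction != 0) {
    for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
      const double tmp =
          next_one_portion * (depth + 1) / ((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction * (depth - i) /
                                               static_cast<double>(depth + 1);
    }
  } else {
    for (int i = static_cast<int>(depth) - 1; i >= 0; --i) {
      total += path[i].pweight * (depth + 1) / (zero_fraction * (depth - i));
    }
  }
  return total;
}

void tree_shap_recursive(const Tree& t, const double* x, double* phi,
                         int node, unsigned depth, PathElement* parent_path,
                         double parent_zero_fraction,
                         double parent_one_fraction, int parent_feature) {
  PathElement* path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, parent_zero_fraction, parent_one_fraction,
              parent_feature);

  if (t.feature[node] < 0) {  // leaf
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * t.value[node];
    }
    return;
  }

  const int split_feature = t.feature[node];
  const int hot = (x[split_feature] <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  const int cold = (hot == t.left[node]) ? t.right[node] : t.left[node];
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot] / w;
  const double cold_zero_fraction = t.cover[cold] / w;
  double incoming_zero_fraction = 1, incoming_one_fraction = 1;

  // features may repeat along a path: undo the previous split on this one
  unsigned path_index = 0;
  for (; path_index <= depth; ++path_index)
    if (path[path_index].feature_index == split_feature) break;
  if (path_index != depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, depth, path_index);
    depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, depth + 1, path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(t, x, phi, cold, depth + 1, path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature);
}

}  // namespace

// Fit a bootstrap forest.  mtry features are drawn at every split; out-of-bag
// rows of each tree supply the skill estimate: R^2 = 1 - SSE/SST with SST
// about the mean of the targets that received at least one OOB prediction.
// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_leaf, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y sizes differ");
  if (n < 2) stop("need at least 2 samples");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");

  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  List trees(ntree);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0), inbag(n);

  for (int b = 0; b < ntree; ++b) {
    Builder bd(X, y, mtry, min_leaf, rng);
    bd.idx.resize(n);
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int r = rng.below(n);
      bd.idx[i] = r;
      inbag[r] = 1;
    }
    bd.make_node(0, n, 0);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_tree(bd.tree, X, i);
        oob_cnt[i] += 1;
      }
    }
    trees[b] = tree_to_list(bd.tree);
  }

  double ybar = 0;
  int n_oob = 0;
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) { ybar += y[i]; ++n_oob; }
  double oob_r2 = NA_REAL;
  NumericVector oob_pred(n, NA_REAL);
  if (n_oob > 0) {
    ybar /= n_oob;
    double sse = 0, sst = 0;
    for (int i = 0; i < n; ++i) {
      if (oob_cnt[i] == 0) continue;
      const double pred = oob_sum[i] / oob_cnt[i];
      oob_pred[i] = pred;
      sse += (y[i] - pred) * (y[i] - pred);
      sst += (y[i] - ybar) * (y[i] - ybar);
    }
    if (sst > 0) oob_r2 = 1.0 - sse / sst;
  }
  return List::create(_["trees"] = trees, _["oob_r2"] = oob_r2,
                      _["oob_pred"] = oob_pred, _["n_oob"] = n_oob);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  std::vector<Tree> forest;
  forest.reserve(ntree);
  for (int b = 0; b < ntree; ++b) forest.push_back(tree_from_list(trees[b]));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int b = 0; b < ntree; ++b) s += predict_tree(forest[b], X, i);
    out[i] = s / ntree;
  }
  return out;
}

// Per-row, per-feature SHAP contributions averaged over trees, plus the
// expected value (root mean averaged over trees).  Additivity:
// base + rowSums(phi) equals the forest prediction to float precision.
// [[Rcpp::export]]
List rf_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  std::vector<Tree> forest;
  forest.reserve(ntree);
  int maxd = 0;
  double base = 0;
  for (int b = 0; b < ntree; ++b) {
    forest.push_back(tree_from_list(trees[b]));
    maxd = std::max(maxd, forest[b].max_depth);
    base += forest[b].value[0];
  }
  base /= ntree;

  const unsigned md = static_cast<unsigned>(maxd) + 2;
  std::vector<PathElement> buf((md + 1) * (md + 2) / 2 + md + 2);
  NumericMatrix phi(n, p);
  std::vector<double> row_x(p), row_phi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row_x[j] = X(i, j);
    std::fill(row_phi.begin(), row_phi.end(), 0.0);
    for (int b = 0; b < ntree; ++b) {
      const Tree& t = forest[b];
      if (t.feature[0] < 0) continue;  // stump contributes nothing
      tree_shap_recursive(t, row_x.data(), row_phi.data(), 0, 0, buf.data(),
                          1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = row_phi[j] / ntree;
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
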