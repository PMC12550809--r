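// Regression trees for tree-ensemble breakthrough models.
//
// A tree is passed to/from R as a list of parallel vectors:
//   feature   int,    -1 for leaves
//   threshold double, split is x <= threshold -> left
//   left/right int,   child node indices (0-based)
//   value     double, node mean of training y
//   cover     double, number of training samples reaching the node
//
// Fitting is greedy CART (variance reduction) with per-node feature
// subsampling (mtry) and an optional extra-trees style random threshold.
// Feature subsampling uses R's RNG so set.seed() on the R side makes fits
// bit-reproducible. Bootstrap/weighted resampling is done by the caller,
// which passes the index multiset.
//
// SHAP attributions use the path-dependent TreeSHAP recursion: exact
// Shapley values for the tree's conditional-expectation game defined by
// node covers, in polynomial time.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct BuildNode {
  std::vector<int> idx;
  int depth;
  int pos;  // index into output arrays
};

struct TreeArrays {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value, cover, gain;
};

// best SSE-reducing split on one feature; returns gain (>0) or -1
bool best_split_feature(const NumericMatrix& X, const NumericVector& y,
                        const std::vector<int>& idx, int f, int min_leaf,
                        bool random_split, double& gain, double& thr) {
  const int n = idx.size();
  std::vector<std::pair<double, double>> xv(n);  // (x, y)
  for (int i = 0; i < n; ++i)
    xv[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
  std::sort(xv.begin(), xv.end());
  if (xv.front().first == xv.back().first) return false;

  double stot = 0.0;
  for (int i = 0; i < n; ++i) stot += xv[i].second;

  if (random_split) {
    // extra-trees: one uniform threshold in (min, max)
    double lo = xv.front().first, hi = xv.back().first;
    thr = lo + unif_rand() * (hi - lo);
    if (thr >= hi) thr = std::nextafter(hi, lo);
    double sl = 0.0; int nl = 0;
    for (int i = 0; i < n; ++i) {
      if (xv[i].first <= thr) { sl += xv[i].second; ++nl; }
    }
    if (nl < min_leaf || n - nl < min_leaf) return false;
    double sr = stot - sl;
    gain = sl * sl / nl + sr * sr / (n - nl) - stot * stot / n;
    return true;
  }

  double best = -1.0, sl = 0.0;
  int bi = -1;
  for (int i = 0; i < n - 1; ++i) {
    sl += xv[i].second;
    if (xv[i].first == xv[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    double sr = stot - sl;
    double sc = sl * sl / nl + sr * sr / nr;
    if (sc > best) { best = sc; bi = i; }
  }
  if (bi < 0) return false;
  gain = best - stot * stot / n;
  thr = 0.5 * (xv[bi].first + xv[bi + 1].first);
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, IntegerVector idx0,
                  int mtry, int max_depth, int min_split, int min_leaf,
                  bool random_split) {
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  TreeArrays t;
  std::vector<BuildNode> stack;
  std::vector<int> root_idx(idx0.begin(), idx0.end());  // 0-based from R side

  auto new_node = [&](void) -> int {
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.value.push_back(0.0);
    t.cover.push_back(0.0);
    t.gain.push_back(0.0);
    return (int)t.feature.size() - 1;
  };

  int root = new_node();
  stack.push_back({std::move(root_idx), 0, root});
  std::vector<int> feats(p);

  while (!stack.empty()) {
    BuildNode nd = std::move(stack.back());
    stack.pop_back();
    const std::vector<int>& idx = nd.idx;
    const int n = idx.size();

    double s = 0.0;
    for (int i = 0; i < n; ++i) s += y[idx[i]];
    t.value[nd.pos] = s / n;
    t.cover[nd.pos] = n;

    bool pure = true;
    for (int i = 1; i < n && pure; ++i)
      if (y[idx[i]] != y[idx[0]]) pure = false;
    if (n < min_split || n < 2 * min_leaf ||
        (max_depth >= 0 && nd.depth >= max_depth) || pure)
      continue;

    // sample mtry features without replacement (R RNG, partial shuffle)
    for (int i = 0; i < p; ++i) feats[i] = i;
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(feats[i], feats[j]);
    }

    double best_gain = 1e-12, thr = 0.0;
    int best_f = -1;
    double best_thr = 0.0;
    for (int k = 0; k < mtry; ++k) {
      double gain;
      if (best_split_feature(X, y, idx, feats[k], min_leaf, random_split,
                             gain, thr) && gain > best_gain) {
        best_gain = gain;
        best_f = feats[k];
        best_thr = thr;
      }
    }
    if (best_f < 0) continue;

    std::vector<int> li, ri;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) continue;

    int l = new_node(), r = new_node();
    t.feature[nd.pos] = best_f;
    t.gain[nd.pos] = best_gain;
    t.threshold[nd.pos] = best_thr;
    t.left[nd.pos] = l;
    t.right[nd.pos] = r;
    stack.push_back({std::move(ri), nd.depth + 1, r});
    stack.push_back({std::move(li), nd.depth + 1, l});
  }

  return List::create(_["feature"] = t.feature,
                      _["threshold"] = t.threshold,
                      _["left"] = t.left, _["right"] = t.right,
                      _["value"] = t.value, _["cover"] = t.cover,
                      _["gain"] = t.gain);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int j = 0;
    while (feature[j] >= 0)
      j = (X(i, feature[j]) <= threshold[j]) ? left[j] : right[j];
    out[i] = value[j];
  }
  return out;
}

namespace {

struct PathElem {
  int d;
  double z, o, w;
};

void path_extend(std::vector<PathElem>& m, double pz, double po, int pi) {
  const int l = m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

std::vector<PathElem> path_unwind(const std::vector<PathElem>& m, int i) {
  const int l = (int)m.size() - 1;
  std::vector<PathElem> out(m.begin(), m.end() - 1);
  double n = m[l].w;
  if (m[i].o != 0.0) {
    for (int j = l - 1; j >= 0; --j) {
      double t = out[j].w;
      out[j].w = n * (l + 1) / ((j + 1) * m[i].o);
      n = t - out[j].w * m[i].z * (l - j) / (double)(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      out[j].w = out[j].w * (l + 1) / (m[i].z * (l - j));
  }
  for (int j = i; j < l; ++j) {
    out[j].d = m[j + 1].d;
    out[j].z = m[j + 1].z;
    out[j].o = m[j + 1].o;
  }
  return out;
}

// sum of the unwound path weights without materializing the unwound path
// (hot path: called once per leaf and path element)
double unwound_sum(const std::vector<PathElem>& m, int i) {
  const int l = (int)m.size() - 1;
  double total = 0.0;
  if (m[i].o != 0.0) {
    double n = m[l].w;
    for (int j = l - 1; j >= 0; --j) {
      double t = n * (l + 1) / ((j + 1) * m[i].o);
      total += t;
      n = m[j].w - t * m[i].z * (l - j) / (double)(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      total += m[j].w * (l + 1) / (m[i].z * (l - j));
  }
  return total;
}

struct ShapCtx {
  const IntegerVector* feature;
  const IntegerVector* left;
  const IntegerVector* right;
  const NumericVector* threshold;
  const NumericVector* value;
  const NumericVector* cover;
  const double* x;
  double* phi;
};

void shap_recurse(const ShapCtx& c, int j, std::vector<PathElem> m,
                  double pz, double po, int pi) {
  path_extend(m, pz, po, pi);
  const int f = (*c.feature)[j];
  if (f < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      c.phi[m[i].d] +=
          unwound_sum(m, i) * (m[i].o - m[i].z) * (*c.value)[j];
    }
    return;
  }
  const int l = (*c.left)[j], r = (*c.right)[j];
  int hot = (c.x[f] <= (*c.threshold)[j]) ? l : r;
  int cold = (hot == l) ? r : l;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 0; i < (int)m.size(); ++i)
    if (m[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    m = path_unwind(m, k);
  }
  const double cj = (*c.cover)[j];
  shap_recurse(c, hot, m, iz * (*c.cover)[hot] / cj, io, f);
  shap_recurse(c, cold, m, iz * (*c.cover)[cold] / cj, 0.0, f);
}

}  // namespace

// [[Rcpp::export]]
List cpp_tree_shap(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"],
                cover = tree["cover"];
  const int n = X.nrow(), p = X.ncol();

  // base value: cover-weighted mean over leaves
  double base = 0.0;
  for (int j = 0; j < feature.size(); ++j)
    if (feature[j] < 0) base += value[j] * cover[j];
  base /= cover[0];

  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  ShapCtx c;
  c.feature = &feature; c.left = &left; c.right = &right;
  c.threshold = &threshold; c.value = &value; c.cover = &cover;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < p; ++k) xrow[k] = X(i, k);
    std::vector<double> ph(p, 0.0);
    c.x = xrow.data();
    c.phi = ph.data();
    shap_recurse(c, 0, std::vector<PathElem>(), 1.0, 1.0, -1);
    for (int k = 0; k < p; ++k) phi(i, k) = ph[k];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
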