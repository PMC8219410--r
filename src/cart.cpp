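#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART classification tree with per-node random feature subsampling,
// Gini impurity splits at midpoints between distinct values, grown until
// pure or until min_samples_leaf forbids a split; no pruning.
//
// Randomness comes from R's RNG (RNGScope via Rcpp attributes), so trees
// are reproducible under set.seed() on the R side.
//
// Tie-breaking is fully deterministic: candidate features are scanned in
// ascending index order and thresholds in ascending value order, and a
// split is only accepted on a strict impurity improvement, so equal-gain
// ties resolve to the lowest feature index, then the smallest threshold.
// Leaf classes are the majority class; ties resolve to the lower class.

struct NodeRec {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // 0-based node indices, -1 for leaf
  int klass;        // majority class at the node
};

static int majority(const std::vector<int>& counts) {
  int best = 0;
  for (size_t c = 1; c < counts.size(); ++c)
    if (counts[c] > counts[best]) best = (int)c;
  return best;
}

// [[Rcpp::export]]
List build_cart_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                    int max_features, int min_samples_leaf,
                    IntegerVector rows) {
  const int p = X.ncol();
  const int m0 = rows.size();
  if (m0 < 1) stop("build_cart_cpp: empty sample");
  if (max_features < 1 || max_features > p)
    stop("max_features must be in 1..%d", p);
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1");

  std::vector<int> idx(rows.begin(), rows.end());
  std::vector<NodeRec> nodes;
  // stack of (node id, begin, end) over idx
  struct Task { int node, begin, end; };
  std::vector<Task> stack;
  nodes.push_back(NodeRec{-1, 0.0, -1, -1, 0});
  stack.push_back(Task{0, 0, m0});

  std::vector<int> feats(p);
  std::vector<std::pair<double, int> > vals;
  std::vector<int> cl(n_classes), cr(n_classes), cnt(n_classes);

  while (!stack.empty()) {
    Task t = stack.back();
    stack.pop_back();
    const int m = t.end - t.begin;

    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = t.begin; i < t.end; ++i) cnt[y[idx[i]]]++;
    const int maj = majority(cnt);
    nodes[t.node].klass = maj;

    bool pure = (cnt[maj] == m);
    if (pure || m < 2 * min_samples_leaf) {
      nodes[t.node].feature = -1;
      continue;
    }

    // draw max_features distinct features (partial Fisher-Yates), then sort
    for (int i = 0; i < p; ++i) feats[i] = i;
    for (int i = 0; i < max_features; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(feats[i], feats[j]);
    }
    std::sort(feats.begin(), feats.begin() + max_features);

    double best_imp = R_PosInf;
    int best_f = -1;
    double best_thr = 0.0;

    for (int fi = 0; fi < max_features; ++fi) {
      const int f = feats[fi];
      vals.clear();
      vals.reserve(m);
      for (int i = t.begin; i < t.end; ++i)
        vals.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      std::fill(cl.begin(), cl.end(), 0);
      cr = cnt;
      double ssl = 0.0;            // sum of squared left counts
      double ssr = 0.0;
      for (int c = 0; c < n_classes; ++c) ssr += (double)cnt[c] * cnt[c];

      for (int i = 0; i < m - 1; ++i) {
        const int c = vals[i].second;
        ssl += 2.0 * cl[c] + 1.0;
        cl[c]++;
        ssr -= 2.0 * cr[c] - 1.0;
        cr[c]--;
        const int nl = i + 1, nr = m - nl;
        if (vals[i + 1].first == vals[i].first) continue;
        if (nl < min_samples_leaf || nr < min_samples_leaf) continue;
        const double imp = (nl - ssl / nl) + (nr - ssr / nr);
        if (imp < best_imp - 1e-12) {
          best_imp = imp;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_f < 0) {  // no admissible split among the drawn features
      nodes[t.node].feature = -1;
      continue;
    }

    // partition idx[begin, end) by x <= threshold, preserving order
    std::stable_partition(idx.begin() + t.begin, idx.begin() + t.end,
                          [&](int r) { return X(r, best_f) <= best_thr; });
    int mid = t.begin;
    while (mid < t.end && X(idx[mid], best_f) <= best_thr) ++mid;

    const int li = (int)nodes.size();
    nodes.push_back(NodeRec{-1, 0.0, -1, -1, maj});
    const int ri = (int)nodes.size();
    nodes.push_back(NodeRec{-1, 0.0, -1, -1, maj});
    nodes[t.node].feature = best_f;
    nodes[t.node].threshold = best_thr;
    nodes[t.node].left = li;
    nodes[t.node].right = ri;
    // push right first so left is processed first (deterministic layout)
    stack.push_back(Task{ri, mid, t.end});
    stack.push_back(Task{li, t.begin, mid});
  }

  const int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), klass(nn);
  NumericVector threshold(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    klass[i] = nodes[i].klass;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["klass"] = klass);
}

// [[Rcpp::export]]
IntegerVector predict_cart_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  IntegerVector klass = tree["klass"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = klass[node];
  }
  return out;
}
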