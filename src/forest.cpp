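// CART random forest (regression + classification) used for microbiota-age
// regression, age-discriminatory taxa ranking, and cross-validated group
// classification. Uses R's RNG so set.seed() on the R side makes fits
// reproducible. Single-threaded by design.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 => leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;     // leaf: mean response (reg) or class index
};

inline int runif_int(int n) {
  // integer in [0, n)
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

void sample_features(int p, int mtry, std::vector<int> &pool,
                     std::vector<int> &out) {
  // partial Fisher-Yates on a reusable pool 0..p-1
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < mtry; ++i) {
    int j = i + runif_int(p - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct Builder {
  const NumericMatrix &X;
  const NumericVector &y;   // class index as double when classification
  bool classify;
  int nclass;
  int mtry;
  int min_node;
  int max_depth;
  TreeNodes tree;
  std::vector<double> &importance; // impurity decrease accumulator, length p

  Builder(const NumericMatrix &X_, const NumericVector &y_, bool cls,
          int ncls, int mtry_, int min_node_, int max_depth_,
          std::vector<double> &imp)
      : X(X_), y(y_), classify(cls), nclass(ncls), mtry(mtry_),
        min_node(min_node_), max_depth(max_depth_), importance(imp) {}

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    return (int)tree.feature.size() - 1;
  }

  double leaf_value(const std::vector<int> &idx) {
    if (classify) {
      std::vector<int> cnt(nclass, 0);
      for (int i : idx) cnt[(int)y[i]]++;
      int best = 0;
      for (int k = 1; k < nclass; ++k)
        if (cnt[k] > cnt[best]) best = k;
      return (double)best;
    }
    double s = 0.0;
    for (int i : idx) s += y[i];
    return s / idx.size();
  }

  // returns node id
  int build(std::vector<int> &idx, int depth) {
    int node = new_node();
    int n = (int)idx.size();

    bool pure = true;
    for (int i = 1; i < n; ++i)
      if (y[idx[i]] != y[idx[0]]) { pure = false; break; }

    if (n < 2 * min_node || pure || depth >= max_depth) {
      tree.value[node] = leaf_value(idx);
      return node;
    }

    // node impurity bookkeeping
    double best_gain = 0.0;
    int best_f = -1;
    double best_thr = 0.0;

    static thread_local std::vector<int> pool, feats;
    if ((int)pool.size() < X.ncol()) pool.resize(X.ncol());
    std::vector<int> feat_sel;
    sample_features(X.ncol(), mtry, pool, feat_sel);

    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> cntL(classify ? nclass : 0), cntT(classify ? nclass : 0);

    double sumT = 0.0;
    if (!classify)
      for (int i : idx) sumT += y[i];
    else {
      std::fill(cntT.begin(), cntT.end(), 0);
      for (int i : idx) cntT[(int)y[i]]++;
    }

    for (int f : feat_sel) {
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), idx[i]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      if (!classify) {
        double sumL = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          sumL += y[vals[i].second];
          if (vals[i + 1].first == vals[i].first) continue;
          int nL = i + 1, nR = n - nL;
          if (nL < min_node || nR < min_node) continue;
          double sumR = sumT - sumL;
          // gain = decrease in SS relative to parent (up to constant)
          double gain = sumL * sumL / nL + sumR * sumR / nR - sumT * sumT / n;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      } else {
        std::fill(cntL.begin(), cntL.end(), 0);
        double gT = 0.0;
        for (int k = 0; k < nclass; ++k) gT += (double)cntT[k] * cntT[k];
        for (int i = 0; i < n - 1; ++i) {
          cntL[(int)y[vals[i].second]]++;
          if (vals[i + 1].first == vals[i].first) continue;
          int nL = i + 1, nR = n - nL;
          if (nL < min_node || nR < min_node) continue;
          double gL = 0.0, gR = 0.0;
          for (int k = 0; k < nclass; ++k) {
            double cR = cntT[k] - cntL[k];
            gL += (double)cntL[k] * cntL[k];
            gR += cR * cR;
          }
          // Gini gain up to constant: sum n_c^2 / n maximized
          double gain = gL / nL + gR / nR - gT / n;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }

    if (best_f < 0) {
      tree.value[node] = leaf_value(idx);
      return node;
    }

    importance[best_f] += best_gain;

    std::vector<int> idxL, idxR;
    idxL.reserve(n);
    idxR.reserve(n);
    for (int i : idx)
      if (X(i, best_f) <= best_thr) idxL.push_back(i);
      else idxR.push_back(i);

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(idxL, depth + 1);
    int r = build(idxR, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double tree_predict_row(const NumericMatrix &tr, const NumericMatrix &X,
                        int row) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    if (X(row, (int)tr(node, 0)) <= tr(node, 1))
      node = (int)tr(node, 2);
    else
      node = (int)tr(node, 3);
  }
  return tr(node, 4);
}

NumericMatrix pack_tree(const TreeNodes &t) {
  int m = (int)t.feature.size();
  NumericMatrix out(m, 5);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = t.feature[i];
    out(i, 1) = t.threshold[i];
    out(i, 2) = t.left[i];
    out(i, 3) = t.right[i];
    out(i, 4) = t.value[i];
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth, bool classify, int nclass) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);

  List trees(ntree);
  // OOB accumulators
  NumericVector oob_sum(n), oob_n(n);
  NumericMatrix oob_votes(n, classify ? nclass : 1);

  std::vector<int> inbag(n);
  std::vector<int> idx;
  idx.reserve(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int j = runif_int(n);
      inbag[j]++;
      idx.push_back(j);
    }
    Builder b(X, y, classify, nclass, mtry, min_node, max_depth, importance);
    b.build(idx, 0);
    NumericMatrix tr = pack_tree(b.tree);
    trees[t] = tr;
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        double v = tree_predict_row(tr, X, i);
        if (classify)
          oob_votes(i, (int)v) += 1.0;
        else
          oob_sum[i] += v;
        oob_n[i] += 1.0;
      }
    }
  }

  NumericVector imp(p);
  for (int f = 0; f < p; ++f) imp[f] = importance[f] / ntree;

  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_sum"] = oob_sum, _["oob_n"] = oob_n,
                      _["oob_votes"] = oob_votes);
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, bool classify,
                             int nclass) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, classify ? nclass : 1);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      double v = tree_predict_row(tr, X, i);
      if (classify)
        out(i, (int)v) += 1.0;
      else
        out(i, 0) += v;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < out.ncol(); ++k) out(i, k) /= ntree;
  return out;
}
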