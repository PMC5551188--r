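// Bagged CART regression forest with variance-reduction splits.
//
// All randomness is drawn from R's RNG stream via R::runif(0,1) in a fixed,
// documented order so that a pure-R reference implementation seeded
// identically reproduces the ensemble bit-for-bit:
//
//   for each tree t = 1..ntree:
//     1. n bootstrap draws: idx_i = floor(runif() * n), i = 1..n
//     2. depth-first tree growth (node, then left child, then right child);
//        at each splittable node, mtry candidate variables are drawn without
//        replacement by a partial Fisher-Yates shuffle of 0..p-1:
//          for k in 0..mtry-1: j = k + floor(runif() * (p - k)); swap(k, j)
//        candidates are examined in drawn order; the best split strictly
//        minimises SSE_left + SSE_right; ties keep the earlier candidate /
//        smaller threshold.
//
// A node becomes a leaf when its size < min_split or its responses are
// constant or no candidate variable varies within the node. Split thresholds
// are midpoints between consecutive distinct sorted values; children may be
// any size >= 1.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;       // split variable (0-based), -1 for leaf
  std::vector<double> split;  // threshold, x <= split goes left
  std::vector<int> left, right;
  std::vector<double> value;  // node mean (prediction for leaves)
};

struct Grower {
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry, min_split, max_depth;  // max_depth 0 = unlimited
  Tree tree;
  std::vector<int> pool;

  Grower(const NumericMatrix &X_, const NumericVector &y_, int mtry_,
         int min_split_, int max_depth_)
      : X(X_), y(y_), mtry(mtry_), min_split(min_split_),
        max_depth(max_depth_), pool(X_.ncol()) {}

  int new_node(double mean) {
    tree.var.push_back(-1);
    tree.split.push_back(NA_REAL);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(mean);
    return (int)tree.var.size() - 1;
  }

  // rows: bootstrap sample indices reaching this node (with multiplicity)
  int grow(std::vector<int> &rows, int depth) {
    const int nn = (int)rows.size();
    double sum = 0.0;
    for (int i = 0; i < nn; ++i) sum += y[rows[i]];
    const double mean = sum / nn;
    const int node = new_node(mean);

    bool const_y = true;
    for (int i = 1; i < nn; ++i)
      if (y[rows[i]] != y[rows[0]]) { const_y = false; break; }
    if (nn < min_split || const_y) return node;
    if (max_depth > 0 && depth >= max_depth) return node;

    const int p = X.ncol();
    const int m = std::min(mtry, p);
    for (int k = 0; k < p; ++k) pool[k] = k;
    for (int k = 0; k < m; ++k) {
      int j = k + (int)(R::runif(0.0, 1.0) * (p - k));
      if (j >= p) j = p - 1;
      std::swap(pool[k], pool[j]);
    }

    // Order rows canonically by (value, row index) per candidate and use a
    // fixed accumulation sequence for the split criterion (sequential adds
    // for the left sums, sequential subtractions from the node total for
    // the right sums). The canonical arithmetic makes results reproducible
    // bit-for-bit by a reference implementation even when two candidate
    // splits induce mathematically identical partitions.
    double best_crit = R_PosInf;
    int best_var = -1;
    double best_split = 0.0;
    std::vector<int> ord(rows);
    std::vector<double> ys(nn);

    for (int k = 0; k < m; ++k) {
      const int v = pool[k];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, v) < X(b, v) || (X(a, v) == X(b, v) && a < b);
      });
      if (X(ord[0], v) == X(ord[nn - 1], v)) continue;  // constant in node
      for (int i = 0; i < nn; ++i) ys[i] = y[ord[i]];
      double sl = 0.0, ssl = 0.0;
      double sr = 0.0, ssr = 0.0;
      for (int i = 0; i < nn; ++i) { sr += ys[i]; ssr += ys[i] * ys[i]; }
      for (int i = 0; i < nn - 1; ++i) {
        const double yi = ys[i];
        sl += yi; ssl += yi * yi;
        sr -= yi; ssr -= yi * yi;
        const double xa = X(ord[i], v), xb = X(ord[i + 1], v);
        if (xa == xb) continue;
        const int nl = i + 1, nr = nn - nl;
        const double crit = (ssl - sl * sl / nl) + (ssr - sr * sr / nr);
        if (crit < best_crit) {
          best_crit = crit;
          best_var = v;
          // midpoint threshold; if rounding collapses it onto xb (adjacent
          // doubles), fall back to xa so both children stay non-empty
          double mid = (xa + xb) / 2.0;
          if (!(mid < xb)) mid = xa;
          best_split = mid;
        }
      }
    }
    if (best_var < 0) return node;  // nothing to split on

    std::vector<int> lrows, rrows;
    lrows.reserve(nn); rrows.reserve(nn);
    for (int i = 0; i < nn; ++i) {
      if (X(rows[i], best_var) <= best_split) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    tree.var[node] = best_var;
    tree.split[node] = best_split;
    tree.left[node] = grow(lrows, depth + 1);
    tree.right[node] = grow(rrows, depth + 1);
    return node;
  }
};

double predict_one(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.var[node] >= 0)
    node = (X(row, t.var[node]) <= t.split[node]) ? t.left[node] : t.right[node];
  return t.value[node];
}

Tree tree_from_list(const List &tl) {
  Tree t;
  IntegerVector var = tl["var"], left = tl["left"], right = tl["right"];
  NumericVector split = tl["split"], value = tl["value"];
  t.var.assign(var.begin(), var.end());
  t.split.assign(split.begin(), split.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.value.assign(value.begin(), value.end());
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_split, int max_depth) {
  const int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(R::runif(0.0, 1.0) * n);
      if (j >= n) j = n - 1;
      rows[i] = j;
      inbag(j, t)++;
    }
    Grower g(X, y, mtry, min_split, max_depth);
    g.grow(rows, 0);
    trees[t] = List::create(
        _["var"] = IntegerVector(g.tree.var.begin(), g.tree.var.end()),
        _["split"] = NumericVector(g.tree.split.begin(), g.tree.split.end()),
        _["left"] = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
        _["right"] = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
        _["value"] = NumericVector(g.tree.value.begin(), g.tree.value.end()));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_tree_cpp(List tl, NumericMatrix X) {
  Tree tr = tree_from_list(tl);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = predict_one(tr, X, i);
  return out;
}

// [[Rcpp::export]]
NumericVector rf_oob_predict_cpp(List trees, IntegerMatrix inbag,
                                 NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector sum(n);
  IntegerVector cnt(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        sum[i] += predict_one(tr, X, i);
        cnt[i]++;
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return out;
}

// Permutation importance. mode 0 = marginal, 1 = conditional (Strobl-style:
// the permuted variable is shuffled within strata formed by partitioning the
// tree's out-of-bag rows on the split points that correlated covariates use
// in that tree). cond[, j] marks, for target variable j, which variables
// count as correlated. Permutation order is drawn from R's RNG.
// [[Rcpp::export]]
NumericVector rf_importance_cpp(List trees, IntegerMatrix inbag,
                                NumericMatrix X, NumericVector y, int mode,
                                LogicalMatrix cond) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericVector imp(p);
  IntegerVector used(p);
  NumericMatrix Xp(clone(X));

  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int no = (int)oob.size();
    if (no < 2) continue;

    double err0 = 0.0;
    for (int i = 0; i < no; ++i) {
      double d = predict_one(tr, X, oob[i]) - y[oob[i]];
      err0 += d * d;
    }
    err0 /= no;

    for (int j = 0; j < p; ++j) {
      // strata: one group (marginal) or refinement by correlated cutpoints
      std::vector<std::vector<int> > groups;
      groups.push_back(oob);
      if (mode == 1) {
        for (size_t nd = 0; nd < tr.var.size(); ++nd) {
          const int v = tr.var[nd];
          if (v < 0 || v == j || !cond(v, j)) continue;
          const double s = tr.split[nd];
          std::vector<std::vector<int> > next;
          next.reserve(groups.size() * 2);
          for (size_t g = 0; g < groups.size(); ++g) {
            std::vector<int> lo, hi;
            for (size_t i = 0; i < groups[g].size(); ++i) {
              if (X(groups[g][i], v) <= s) lo.push_back(groups[g][i]);
              else hi.push_back(groups[g][i]);
            }
            if (!lo.empty()) next.push_back(lo);
            if (!hi.empty()) next.push_back(hi);
          }
          groups.swap(next);
        }
      }

      // permute variable j within each group (Fisher-Yates, R RNG)
      for (size_t g = 0; g < groups.size(); ++g) {
        const std::vector<int> &grp = groups[g];
        const int m = (int)grp.size();
        std::vector<double> vals(m);
        for (int i = 0; i < m; ++i) vals[i] = X(grp[i], j);
        for (int i = m - 1; i > 0; --i) {
          int k = (int)(R::runif(0.0, 1.0) * (i + 1));
          if (k > i) k = i;
          std::swap(vals[i], vals[k]);
        }
        for (int i = 0; i < m; ++i) Xp(grp[i], j) = vals[i];
      }

      double err1 = 0.0;
      for (int i = 0; i < no; ++i) {
        double d = predict_one(tr, Xp, oob[i]) - y[oob[i]];
        err1 += d * d;
      }
      err1 /= no;
      imp[j] += err1 - err0;
      used[j]++;
      for (int i = 0; i < no; ++i) Xp(oob[i], j) = X(oob[i], j);  // restore
    }
  }
  for (int j = 0; j < p; ++j) imp[j] = used[j] > 0 ? imp[j] / used[j] : NA_REAL;
  return imp;
}
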