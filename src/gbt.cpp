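// Second-order gradient boosting for binary classification with
// xgboost-style regularization, plus exact path-dependent tree SHAP.
//
// The learner is intentionally small: dense feature matrices without
// missing values (imputation happens upstream), exact greedy split search,
// depth-wise growth.  Row/column subsamples are drawn in R (so all
// randomness flows through R's RNG) and passed in as 0-based index vectors.
//
// SHAP follows the polynomial-time tree-traversal algorithm for
// path-dependent feature perturbation (EXTEND/UNWIND over the active
// feature path), with node covers taken from the full training set.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // split feature, -1 for leaf
  std::vector<double> threshold; // go left if x < threshold
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // leaf weight (eta-scaled); 0 for internal
  std::vector<double> cover;     // full-training row count through the node
};

struct SplitInfo {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

static SplitInfo best_split(const NumericMatrix& X,
                            const std::vector<double>& g,
                            const std::vector<double>& h,
                            const std::vector<int>& rows,
                            const std::vector<int>& feats,
                            double lambda, double gamma,
                            double min_child_weight) {
  const int nr = (int)rows.size();
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  const double parent_score = G * G / (H + lambda);

  SplitInfo best;
  std::vector<std::pair<double, int>> ord(nr);
  for (int f : feats) {
    for (int i = 0; i < nr; ++i)
      ord[i] = std::make_pair(X(rows[i], f), rows[i]);
    std::sort(ord.begin(), ord.end());
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < nr; ++i) {
      GL += g[ord[i].second]; HL += h[ord[i].second];
      if (ord[i].first == ord[i + 1].first) continue;  // no cut within ties
      // min_child_weight = minimum number of instances per child
      if (i + 1 < min_child_weight || nr - i - 1 < min_child_weight) continue;
      const double HR = H - HL;
      const double GR = G - GL;
      const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                 GR * GR / (HR + lambda) - parent_score) -
                          gamma;
      if (gain > 1e-12 && gain > best.gain + 1e-12) {
        best.found = true;
        best.gain = gain;
        best.feature = f;
        best.threshold = (ord[i].first + ord[i + 1].first) / 2.0;
      }
    }
  }
  return best;
}

static int grow_node(Tree& tr, const NumericMatrix& X,
                     const std::vector<double>& g,
                     const std::vector<double>& h,
                     const std::vector<int>& rows, int depth, int max_depth,
                     const std::vector<int>& feats, double lambda,
                     double gamma, double min_child_weight, double eta) {
  const int id = (int)tr.feature.size();
  tr.feature.push_back(-1); tr.threshold.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(0.0); tr.cover.push_back(0.0);

  SplitInfo sp;
  if (depth < max_depth)
    sp = best_split(X, g, h, rows, feats, lambda, gamma, min_child_weight);

  if (!sp.found) {
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    tr.value[id] = -eta * G / (H + lambda);
    return id;
  }
  std::vector<int> lrows, rrows;
  for (int r : rows)
    (X(r, sp.feature) < sp.threshold ? lrows : rrows).push_back(r);
  tr.feature[id] = sp.feature;
  tr.threshold[id] = sp.threshold;
  tr.left[id] = grow_node(tr, X, g, h, lrows, depth + 1, max_depth, feats,
                          lambda, gamma, min_child_weight, eta);
  tr.right[id] = grow_node(tr, X, g, h, rrows, depth + 1, max_depth, feats,
                           lambda, gamma, min_child_weight, eta);
  return id;
}

static double tree_predict_row(const Tree& tr, const NumericMatrix& X,
                               int row) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = X(row, tr.feature[node]) < tr.threshold[node] ? tr.left[node]
                                                         : tr.right[node];
  return tr.value[node];
}

static void fill_cover(Tree& tr, const NumericMatrix& X) {
  const int n = X.nrow();
  for (int r = 0; r < n; ++r) {
    int node = 0;
    tr.cover[node] += 1.0;
    while (tr.feature[node] >= 0) {
      node = X(r, tr.feature[node]) < tr.threshold[node] ? tr.left[node]
                                                         : tr.right[node];
      tr.cover[node] += 1.0;
    }
  }
}

static List tree_to_list(const Tree& tr) {
  return List::create(_["feature"] = wrap(tr.feature),
                      _["threshold"] = wrap(tr.threshold),
                      _["left"] = wrap(tr.left),
                      _["right"] = wrap(tr.right),
                      _["value"] = wrap(tr.value),
                      _["cover"] = wrap(tr.cover));
}

static Tree tree_from_list(const List& l) {
  Tree tr;
  tr.feature = as<std::vector<int>>(l["feature"]);
  tr.threshold = as<std::vector<double>>(l["threshold"]);
  tr.left = as<std::vector<int>>(l["left"]);
  tr.right = as<std::vector<int>>(l["right"]);
  tr.value = as<std::vector<double>>(l["value"]);
  tr.cover = as<std::vector<double>>(l["cover"]);
  return tr;
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                 int max_depth, double gamma, double min_child_weight,
                 double subsample_unused, double lambda, double eta,
                 double base_margin, List row_samples, List col_samples) {
  const int n = X.nrow();
  std::vector<double> margin(n, base_margin);
  List trees(n_estimators);

  for (int t = 0; t < n_estimators; ++t) {
    std::vector<double> g(n), h(n);
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    std::vector<int> rows = as<std::vector<int>>(row_samples[t]);
    std::vector<int> feats = as<std::vector<int>>(col_samples[t]);
    Tree tr;
    grow_node(tr, X, g, h, rows, 0, max_depth, feats, lambda, gamma,
              min_child_weight, eta);
    fill_cover(tr, X);
    for (int i = 0; i < n; ++i) margin[i] += tree_predict_row(tr, X, i);
    trees[t] = tree_to_list(tr);
  }
  return List::create(_["trees"] = trees,
                      _["train_margin"] = wrap(margin));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X,
                              double base_margin) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tr, X, i);
  }
  return out;
}

// ---- path-dependent tree SHAP -------------------------------------------

struct PathElem { int d; double z; double o; double w; };

static void path_extend(std::vector<PathElem>& m, double pz, double po,
                        int pi) {
  const int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (double)(i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (double)(l - i) / (double)(l + 1);
  }
}

static std::vector<PathElem> path_unwind(std::vector<PathElem> m, int i) {
  const int l = (int)m.size() - 1;
  const double one = m[i].o, zero = m[i].z;
  double nx = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (one != 0.0) {
      const double t = m[j].w;
      m[j].w = nx * (double)(l + 1) / ((double)(j + 1) * one);
      nx = t - m[j].w * zero * (double)(l - j) / (double)(l + 1);
    } else {
      m[j].w = m[j].w * (double)(l + 1) / (zero * (double)(l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d; m[j].z = m[j + 1].z; m[j].o = m[j + 1].o;
  }
  m.pop_back();
  return m;
}

static double path_unwound_sum(const std::vector<PathElem>& m, int i) {
  const int l = (int)m.size() - 1;
  const double one = m[i].o, zero = m[i].z;
  double total = 0.0, nx = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (one != 0.0) {
      const double t = nx * (double)(l + 1) / ((double)(j + 1) * one);
      total += t;
      nx = m[j].w - t * zero * (double)(l - j) / (double)(l + 1);
    } else {
      total += m[j].w * (double)(l + 1) / (zero * (double)(l - j));
    }
  }
  return total;
}

static void shap_recurse(const Tree& tr, int node, std::vector<PathElem> m,
                         double pz, double po, int pi,
                         const std::vector<double>& x, double* phi) {
  path_extend(m, pz, po, pi);
  if (tr.feature[node] < 0) {
    for (int i = 1; i < (int)m.size(); ++i)
      phi[m[i].d] += path_unwound_sum(m, i) * (m[i].o - m[i].z) *
                     tr.value[node];
    return;
  }
  const int d = tr.feature[node];
  const bool go_left = x[d] < tr.threshold[node];
  const int hot = go_left ? tr.left[node] : tr.right[node];
  const int cold = go_left ? tr.right[node] : tr.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i)
    if (m[i].d == d) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    m = path_unwind(m, k);
  }
  const double rj = tr.cover[node];
  shap_recurse(tr, hot, m, iz * tr.cover[hot] / rj, io, d, x, phi);
  shap_recurse(tr, cold, m, iz * tr.cover[cold] / rj, 0.0, d, x, phi);
}

static double tree_expected_value(const Tree& tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const double r = tr.cover[node];
  return (tr.cover[tr.left[node]] / r) *
             tree_expected_value(tr, tr.left[node]) +
         (tr.cover[tr.right[node]] / r) *
             tree_expected_value(tr, tr.right[node]);
}

// [[Rcpp::export(name = ".gbt_shap_cpp")]]
List gbt_shap_cpp(List trees, NumericMatrix X, double base_margin,
                  int n_features) {
  const int n = X.nrow();
  NumericMatrix phi(n, n_features);
  double expected = base_margin;
  std::vector<Tree> tv(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    tv[t] = tree_from_list(trees[t]);
    expected += tree_expected_value(tv[t], 0);
  }
  std::vector<double> x(n_features), rowphi(n_features);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n_features; ++j) x[j] = X(i, j);
    std::fill(rowphi.begin(), rowphi.end(), 0.0);
    for (const Tree& tr : tv) {
      std::vector<PathElem> m;
      shap_recurse(tr, 0, m, 1.0, 1.0, -1, x, rowphi.data());
    }
    for (int j = 0; j < n_features; ++j) phi(i, j) = rowphi[j];
  }
  return List::create(_["phi"] = phi, _["base_value"] = expected);
}
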