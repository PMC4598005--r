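// Core of the random survival forest: log-rank split search, Nelson-Aalen
// terminal cumulative hazards, recursive tree growth, bagging and prediction.
// All randomness (bootstrap resamples, per-node mtry draws) goes through R's
// RNG so results are fully reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Risk-set table of one node: distinct event times, events and at-risk counts,
// plus each sample's bucket = index of the largest event time <= its own time
// (-1 if the sample's time precedes every event time).
struct RiskSet {
  std::vector<double> te;   // distinct event times, ascending
  std::vector<int> d;       // events at te[i]
  std::vector<int> a;       // samples whose bucket is i (Y[i] = suffix sum)
  std::vector<int> bucket;  // per node sample, parallel to the index vector
};

RiskSet build_risk_set(const std::vector<int>& idx,
                       const NumericVector& time, const IntegerVector& event) {
  RiskSet rs;
  for (int l : idx)
    if (event[l] == 1) rs.te.push_back(time[l]);
  std::sort(rs.te.begin(), rs.te.end());
  rs.te.erase(std::unique(rs.te.begin(), rs.te.end()), rs.te.end());
  const int T = (int)rs.te.size();
  rs.d.assign(T, 0);
  rs.a.assign(T, 0);
  rs.bucket.resize(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    const int l = idx[k];
    // largest event time <= time[l]
    int b = (int)(std::upper_bound(rs.te.begin(), rs.te.end(), time[l]) -
                  rs.te.begin()) - 1;
    rs.bucket[k] = b;
    if (b >= 0) rs.a[b] += 1;
    if (event[l] == 1) rs.d[b] += 1;  // event times are always present in te
  }
  return rs;
}

// Signed log-rank statistic F for a fixed daughter-1 composition, given
// per-bucket daughter-1 totals. Terms with Y_i == 1 contribute 0 to the
// denominator. Returns false when the denominator is not positive.
bool logrank_from_tables(const RiskSet& rs, const std::vector<int>& a1,
                         const std::vector<int>& d1, double& F) {
  double num = 0.0, den = 0.0;
  double y = 0.0, y1 = 0.0;
  for (int i = (int)rs.te.size() - 1; i >= 0; --i) {
    y += rs.a[i];
    y1 += a1[i];
    const double di = rs.d[i];
    num += d1[i] - y1 * di / y;
    if (y > 1.0) den += (y1 / y) * (1.0 - y1 / y) * ((y - di) / (y - 1.0)) * di;
  }
  if (den <= 0.0 || !R_finite(num)) return false;
  F = num / std::sqrt(den);
  return R_finite(F);
}

struct SplitResult {
  bool valid = false;
  int col = -1;          // 0-based column
  double cut = NA_REAL;
  double F = NA_REAL;
};

// Fenwick tree (1-based) for prefix sums over the event-time buckets; the
// split sweep needs prefix queries of per-bucket totals in O(log T).
struct Fenwick {
  std::vector<double> t;
  explicit Fenwick(int n) : t(n + 1, 0.0) {}
  void reset() { std::fill(t.begin(), t.end(), 0.0); }
  void add(int i, double v) {  // 0-based position
    for (++i; i < (int)t.size(); i += i & -i) t[i] += v;
  }
  double prefix(int i) const {  // sum of positions 0..i (0-based), -1 -> 0
    double s = 0.0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

// Exhaustive split search over the candidate columns of one node: every
// midpoint between consecutive distinct observed values is a candidate cut.
// Best = max |F|; ties broken by lower name rank, then lower cut.
//
// The sweep is incremental: with m_i = d_i/Y_i and
// u_i = d_i (Y_i - d_i) / ((Y_i - 1) Y_i^2) (0 when Y_i = 1), the statistic
// for a daughter-1 composition is
//   num = sum d1_i - sum m_i Y1_i,
//   den = sum u_i Y1_i (Y_i - Y1_i) = SU1 - SU2,
// and moving one sample with bucket b into daughter 1 increments Y1_i for
// all i <= b, so each scalar updates from prefix sums in O(log T).
SplitResult node_best_split(const NumericMatrix& X, const NumericVector& time,
                            const IntegerVector& event,
                            const std::vector<int>& idx, const RiskSet& rs,
                            const IntegerVector& cand_cols,
                            const IntegerVector& name_rank) {
  SplitResult best;
  const int T = (int)rs.te.size();
  const size_t n = idx.size();
  if (T == 0 || n < 2) return best;

  // per-node constants: Y_i, m_i, u_i and their prefix sums
  std::vector<double> Y(T), M(T), UY(T), U(T);
  {
    double y = 0.0;
    for (int i = T - 1; i >= 0; --i) {
      y += rs.a[i];
      Y[i] = y;
    }
    double cm = 0.0, cuy = 0.0, cu = 0.0;
    for (int i = 0; i < T; ++i) {
      const double di = rs.d[i], yi = Y[i];
      const double ui = yi > 1.0 ? di * (yi - di) / ((yi - 1.0) * yi * yi)
                                 : 0.0;
      cm += di / yi;
      cuy += ui * yi;
      cu += ui;
      M[i] = cm;
      UY[i] = cuy;
      U[i] = cu;
    }
  }

  std::vector<std::pair<double, int>> ord(n);  // (x value, position in idx)
  Fenwick bit_u(T), bit_c(T);  // U[b_l] totals and counts by bucket
  double best_abs = -1.0;
  int best_rank = INT_MAX;

  for (int jj = 0; jj < cand_cols.size(); ++jj) {
    const int col = cand_cols[jj];
    for (size_t k = 0; k < n; ++k) ord[k] = {X(idx[k], col), (int)k};
    std::sort(ord.begin(), ord.end());
    if (ord.front().first == ord.back().first) continue;  // constant in node

    bit_u.reset();
    bit_c.reset();
    double N1 = 0.0, SM = 0.0, SU1 = 0.0, SU2 = 0.0, n_in = 0.0;
    size_t k = 0;
    while (k < n) {
      const double v = ord[k].first;
      // move the whole run of equal values into daughter 1
      while (k < n && ord[k].first == v) {
        const int pos = ord[k].second;
        const int b = rs.bucket[pos];
        if (b >= 0) {
          if (event[idx[pos]] == 1) N1 += 1.0;
          SM += M[b];
          SU1 += UY[b];
          // P(b) = sum_{l in D1} U[min(b, b_l)]
          const double P = bit_u.prefix(b - 1) +
                           U[b] * (n_in - bit_c.prefix(b - 1));
          SU2 += 2.0 * P + U[b];
          bit_u.add(b, U[b]);
          bit_c.add(b, 1.0);
          n_in += 1.0;
        }
        ++k;
      }
      if (k == n) break;  // no samples left for daughter 2
      const double cut = (v + ord[k].first) / 2.0;
      const double num = N1 - SM;
      const double den = SU1 - SU2;
      if (den <= 0.0) continue;
      const double F = num / std::sqrt(den);
      if (!R_finite(F)) continue;
      const double af = std::fabs(F);
      const int rnk = name_rank[col];
      if (af > best_abs + 1e-12 ||
          (af > best_abs - 1e-12 &&
           (rnk < best_rank || (rnk == best_rank && cut < best.cut)))) {
        best.valid = true;
        best.col = col;
        best.cut = cut;
        best.F = F;
        best_abs = std::max(af, best_abs);
        best_rank = rnk;
      }
    }
  }
  return best;
}

// Terminal cumulative hazard: Nelson-Aalen (method 1) or -log Kaplan-Meier
// (method 2, survival floored at 1e-12 to keep H finite in all-event leaves).
void terminal_chf(const RiskSet& rs, int method, std::vector<double>& times,
                  std::vector<double>& H) {
  const int T = (int)rs.te.size();
  times.assign(rs.te.begin(), rs.te.end());
  H.assign(T, 0.0);
  double y = 0.0;
  std::vector<double> Y(T);
  for (int i = T - 1; i >= 0; --i) {
    y += rs.a[i];
    Y[i] = y;
  }
  double acc = 0.0, surv = 1.0;
  for (int i = 0; i < T; ++i) {
    if (method == 1) {
      acc += rs.d[i] / Y[i];
    } else {
      surv *= 1.0 - rs.d[i] / Y[i];
      acc = -std::log(std::max(surv, 1e-12));
    }
    H[i] = acc;
  }
}

// Growing tree, stored as parallel flat arrays (split_col == -1 marks a leaf).
struct Tree {
  std::vector<int> split_col, left, right, leaf_id;
  std::vector<double> split_val;
  std::vector<std::vector<double>> leaf_times, leaf_H;
};

int grow_node(Tree& tr, const NumericMatrix& X, const NumericVector& time,
              const IntegerVector& event, std::vector<int>& idx, int mtry,
              int nodesize_min, int chf_method, const IntegerVector& name_rank) {
  const int me = (int)tr.split_col.size();
  tr.split_col.push_back(-1);
  tr.split_val.push_back(NA_REAL);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.leaf_id.push_back(-1);

  RiskSet rs = build_risk_set(idx, time, event);
  SplitResult sp;
  if ((int)idx.size() >= nodesize_min && !rs.te.empty()) {
    const int p = X.ncol();
    IntegerVector cand = Rcpp::sample(p, std::min(mtry, p), false);  // R RNG
    cand = cand - 1;
    std::sort(cand.begin(), cand.end());  // draw order must not matter
    sp = node_best_split(X, time, event, idx, rs, cand, name_rank);
  }

  if (!sp.valid) {
    tr.leaf_id[me] = (int)tr.leaf_times.size();
    std::vector<double> t, H;
    terminal_chf(rs, chf_method, t, H);
    tr.leaf_times.push_back(t);
    tr.leaf_H.push_back(H);
    return me;
  }

  std::vector<int> lidx, ridx;
  for (int l : idx)
    (X(l, sp.col) <= sp.cut ? lidx : ridx).push_back(l);
  idx.clear();
  idx.shrink_to_fit();
  tr.split_col[me] = sp.col;
  tr.split_val[me] = sp.cut;
  const int lch = grow_node(tr, X, time, event, lidx, mtry, nodesize_min,
                            chf_method, name_rank);
  const int rch = grow_node(tr, X, time, event, ridx, mtry, nodesize_min,
                            chf_method, name_rank);
  tr.left[me] = lch;
  tr.right[me] = rch;
  return me;
}

List tree_to_list(const Tree& tr) {
  List lt(tr.leaf_times.size()), lh(tr.leaf_H.size());
  for (size_t i = 0; i < tr.leaf_times.size(); ++i) {
    lt[i] = NumericVector(tr.leaf_times[i].begin(), tr.leaf_times[i].end());
    lh[i] = NumericVector(tr.leaf_H[i].begin(), tr.leaf_H[i].end());
  }
  return List::create(
      _["split_col"] = IntegerVector(tr.split_col.begin(), tr.split_col.end()),
      _["split_val"] = NumericVector(tr.split_val.begin(), tr.split_val.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["leaf_id"] = IntegerVector(tr.leaf_id.begin(), tr.leaf_id.end()),
      _["leaf_times"] = lt, _["leaf_H"] = lh);
}

double step_eval(const NumericVector& times, const NumericVector& H, double t) {
  // right-continuous step function, 0 before the first event time
  int i = (int)(std::upper_bound(times.begin(), times.end(), t) - times.begin());
  return i == 0 ? 0.0 : H[i - 1];
}

}  // namespace

// [[Rcpp::export]]
double cpp_logrank(NumericVector time, IntegerVector event, NumericVector x,
                   double c) {
  std::vector<int> idx(time.size());
  for (int i = 0; i < time.size(); ++i) idx[i] = i;
  RiskSet rs = build_risk_set(idx, time, event);
  if (rs.te.empty()) return NA_REAL;
  const int T = (int)rs.te.size();
  std::vector<int> a1(T, 0), d1(T, 0);
  int n1 = 0;
  for (int i = 0; i < time.size(); ++i) {
    if (x[i] <= c) {
      ++n1;
      if (rs.bucket[i] >= 0) a1[rs.bucket[i]] += 1;
      if (event[i] == 1) d1[rs.bucket[i]] += 1;
    }
  }
  if (n1 == 0 || n1 == time.size()) return NA_REAL;  // empty daughter
  double F;
  if (!logrank_from_tables(rs, a1, d1, F)) return NA_REAL;
  return F;
}

// [[Rcpp::export]]
List cpp_best_split(NumericVector time, IntegerVector event, NumericMatrix X,
                    IntegerVector cand_cols, IntegerVector name_rank) {
  std::vector<int> idx(time.size());
  for (int i = 0; i < time.size(); ++i) idx[i] = i;
  RiskSet rs = build_risk_set(idx, time, event);
  IntegerVector cc = clone(cand_cols);
  cc = cc - 1;
  SplitResult sp = node_best_split(X, time, event, idx, rs, cc, name_rank);
  if (!sp.valid) return List::create(_["valid"] = false);
  return List::create(_["valid"] = true, _["col"] = sp.col + 1,
                      _["cut"] = sp.cut, _["F"] = sp.F);
}

// [[Rcpp::export]]
List cpp_terminal_chf(NumericVector time, IntegerVector event, int method) {
  std::vector<int> idx(time.size());
  for (int i = 0; i < time.size(); ++i) idx[i] = i;
  RiskSet rs = build_risk_set(idx, time, event);
  std::vector<double> t, H;
  terminal_chf(rs, method, t, H);
  return List::create(_["times"] = NumericVector(t.begin(), t.end()),
                      _["H"] = NumericVector(H.begin(), H.end()));
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector time, IntegerVector event,
                    int ntree, int mtry, int nodesize_min, int chf_method,
                    bool bootstrap, IntegerVector name_rank) {
  const int n = X.nrow();
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx.push_back((int)R_unif_index(n));
    } else {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    }
    Tree tr;
    grow_node(tr, X, time, event, idx, mtry, nodesize_min, chf_method,
              name_rank);
    trees[b] = tree_to_list(tr);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X, double t) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector split_col = tr["split_col"], left = tr["left"],
                  right = tr["right"], leaf_id = tr["leaf_id"];
    NumericVector split_val = tr["split_val"];
    List lt = tr["leaf_times"], lh = tr["leaf_H"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (split_col[node] >= 0)
        node = X(i, split_col[node]) <= split_val[node] ? left[node]
                                                        : right[node];
      const int lid = leaf_id[node];
      NumericVector times = lt[lid], H = lh[lid];
      out[i] += step_eval(times, H, t);
    }
  }
  return out / (double)B;
}
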