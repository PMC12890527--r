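#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Neighbor queries for 2D point sets. Brute force per query point, in C,
// which is ample for per-sample sizes this package targets (tests and
// simulations run at n <= ~5e3 per sample). Ties at equal distance are
// broken by ascending point index so downstream permutation machinery is
// reproducible bit-for-bit.

struct NbrRec {
  double d;
  int idx; // 0-based
};

static inline bool nbr_less(const NbrRec& a, const NbrRec& b) {
  if (a.d != b.d) return a.d < b.d;
  return a.idx < b.idx;
}

// k nearest neighbours among (x, y), self excluded.
// Returns list(idx = n x k integer matrix (1-based), dist = n x k numeric).
// k must satisfy 1 <= k <= n - 1 (caller truncates).
// [[Rcpp::export]]
List cpp_knn(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<NbrRec> recs(n > 0 ? n - 1 : 0);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      recs[m].d = std::sqrt(dx * dx + dy * dy);
      recs[m].idx = j;
      ++m;
    }
    std::partial_sort(recs.begin(), recs.begin() + k, recs.begin() + m, nbr_less);
    for (int t = 0; t < k; ++t) {
      idx(i, t) = recs[t].idx + 1;
      dist(i, t) = recs[t].d;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// All neighbours within radius r (self excluded), sorted by (distance, index).
// Flat representation: list(offsets = length n+1 (0-based starts),
// idx = 1-based neighbour indices, dist = distances).
// [[Rcpp::export]]
List cpp_radius(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  const double r2 = r * r;
  std::vector<int> off(n + 1, 0);
  std::vector<int> all_idx;
  std::vector<double> all_d;
  std::vector<NbrRec> recs;
  for (int i = 0; i < n; ++i) {
    recs.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        NbrRec rec;
        rec.d = std::sqrt(d2);
        rec.idx = j;
        recs.push_back(rec);
      }
    }
    std::sort(recs.begin(), recs.end(), nbr_less);
    for (size_t t = 0; t < recs.size(); ++t) {
      all_idx.push_back(recs[t].idx + 1);
      all_d.push_back(recs[t].d);
    }
    off[i + 1] = (int)all_idx.size();
  }
  return List::create(_["offsets"] = wrap(off), _["idx"] = wrap(all_idx),
                      _["dist"] = wrap(all_d));
}

// For each query point, distance to the nearest target point; optionally a
// target index `skip` (1-based position in the target arrays) excluded per
// query via skip_map (0 = no skip). Used for distance-to-type fields.
// [[Rcpp::export]]
NumericVector cpp_nearest_cross(NumericVector xq, NumericVector yq,
                                NumericVector xt, NumericVector yt,
                                IntegerVector skip_map) {
  const int nq = xq.size(), nt = xt.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    const int skip = skip_map[i] - 1;
    for (int j = 0; j < nt; ++j) {
      if (j == skip) continue;
      const double dx = xt[j] - xq[i], dy = yt[j] - yq[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Cross radius query: for each query point, all target points within r,
// sorted by (distance, target index). exclude_pos[i] (1-based, 0 = none)
// marks a target position identical to query i (self) to drop.
// [[Rcpp::export]]
List cpp_radius_cross(NumericVector xq, NumericVector yq,
                      NumericVector xt, NumericVector yt,
                      double r, IntegerVector exclude_pos) {
  const int nq = xq.size(), nt = xt.size();
  const double r2 = r * r;
  std::vector<int> off(nq + 1, 0);
  std::vector<int> all_idx;
  std::vector<double> all_d;
  std::vector<NbrRec> recs;
  for (int i = 0; i < nq; ++i) {
    recs.clear();
    const int skip = exclude_pos[i] - 1;
    for (int j = 0; j < nt; ++j) {
      if (j == skip) continue;
      const double dx = xt[j] - xq[i], dy = yt[j] - yq[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        NbrRec rec;
        rec.d = std::sqrt(d2);
        rec.idx = j;
        recs.push_back(rec);
      }
    }
    std::sort(recs.begin(), recs.end(), nbr_less);
    for (size_t t = 0; t < recs.size(); ++t) {
      all_idx.push_back(recs[t].idx + 1);
      all_d.push_back(recs[t].d);
    }
    off[i + 1] = (int)all_idx.size();
  }
  return List::create(_["offsets"] = wrap(off), _["idx"] = wrap(all_idx),
                      _["dist"] = wrap(all_d));
}
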