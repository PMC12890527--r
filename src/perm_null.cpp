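#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Monte-Carlo label-shuffle null for the directed neighborhood statistic.
// The statistic matrix for a labeling L is
//   stat[a][b] = (sum over edges (i,j) with L_i=a, L_j=b of w_ij)
//               / #{cells i with >=1 neighbour and L_i=a},
// where w_ij = 1/deg(i). Labels are shuffled within each sample group.
// Permutation t is seeded as (master + 10007*t) mod (2^31-1), so results
// are independent of how permutations are partitioned across workers.

static inline uint32_t bounded_rand(std::mt19937& rng, uint32_t n) {
  // rejection sampling: unbiased uniform draw in [0, n)
  const uint32_t limit = UINT32_MAX - (UINT32_MAX % n);
  uint32_t x;
  do {
    x = rng();
  } while (x >= limit);
  return x % n;
}

// [[Rcpp::export]]
List cpp_perm_null(IntegerVector ii, IntegerVector jj, NumericVector ww,
                   IntegerVector lab, int nT, IntegerVector group_of,
                   int n_groups, LogicalVector has_nbr,
                   NumericMatrix obs, int n_perm, int master_seed) {
  const int n = lab.size();
  const int ne = ii.size();
  const int nP = nT * nT;

  std::vector<std::vector<int> > groups(n_groups);
  for (int i = 0; i < n; ++i) groups[group_of[i] - 1].push_back(i);

  std::vector<int> labp(lab.begin(), lab.end()); // 1-based type codes
  std::vector<double> num(nP);
  std::vector<int> den(nT);

  NumericMatrix sum_s(nT, nT), sum_s2(nT, nT);
  IntegerMatrix c_ge(nT, nT), c_le(nT, nT), n_valid(nT, nT);
  const double tol = 1e-12;

  for (int t = 1; t <= n_perm; ++t) {
    const uint32_t seed =
      (uint32_t)(((int64_t)master_seed + 10007LL * t) % 2147483647LL);
    std::mt19937 rng(seed);
    // Fisher-Yates within each sample group
    for (int g = 0; g < n_groups; ++g) {
      std::vector<int>& rows = groups[g];
      const int m = (int)rows.size();
      for (int k = m - 1; k > 0; --k) {
        const int r = (int)bounded_rand(rng, (uint32_t)(k + 1));
        std::swap(labp[rows[k]], labp[rows[r]]);
      }
    }
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0);
    for (int e = 0; e < ne; ++e) {
      num[(labp[ii[e] - 1] - 1) * nT + (labp[jj[e] - 1] - 1)] += ww[e];
    }
    for (int i = 0; i < n; ++i) {
      if (has_nbr[i]) den[labp[i] - 1]++;
    }
    for (int a = 0; a < nT; ++a) {
      if (den[a] == 0) continue;
      for (int b = 0; b < nT; ++b) {
        const double o = obs(a, b);
        if (!R_finite(o)) continue;
        const double s = num[a * nT + b] / den[a];
        sum_s(a, b) += s;
        sum_s2(a, b) += s * s;
        n_valid(a, b)++;
        if (s >= o - tol) c_ge(a, b)++;
        if (s <= o + tol) c_le(a, b)++;
      }
    }
  }
  return List::create(_["sum"] = sum_s, _["sumsq"] = sum_s2,
                      _["n_valid"] = n_valid, _["c_ge"] = c_ge,
                      _["c_le"] = c_le);
}
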