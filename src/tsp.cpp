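#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static std::vector<double> dist_matrix(const NumericVector& x,
                                       const NumericVector& y) {
  int n = x.size();
  std::vector<double> d(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      d[i * n + j] = std::hypot(x[i] - x[j], y[i] - y[j]);
  return d;
}

// Shortest open Hamiltonian path, free endpoints: Held-Karp DP over subsets.
// dp[mask][j] = shortest path visiting exactly the points in mask, ending at j.
// [[Rcpp::export(name = ".tsp_exact_cpp")]]
double tsp_exact_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) return 0.0;
  if (n > 20) stop("exact solver limited to 20 points");
  std::vector<double> d = dist_matrix(x, y);
  const double INF = std::numeric_limits<double>::infinity();
  size_t full = size_t(1) << n;
  std::vector<double> dp(full * n, INF);
  for (int j = 0; j < n; ++j) dp[(size_t(1) << j) * n + j] = 0.0;
  for (size_t mask = 1; mask < full; ++mask) {
    for (int j = 0; j < n; ++j) {
      if (!(mask & (size_t(1) << j))) continue;
      double cur = dp[mask * n + j];
      if (cur == INF) continue;
      for (int k = 0; k < n; ++k) {
        if (mask & (size_t(1) << k)) continue;
        size_t nmask = mask | (size_t(1) << k);
        double cand = cur + d[j * n + k];
        if (cand < dp[nmask * n + k]) dp[nmask * n + k] = cand;
      }
    }
  }
  double best = INF;
  for (int j = 0; j < n; ++j) best = std::min(best, dp[(full - 1) * n + j]);
  return best;
}

static double path_len(const std::vector<int>& ord,
                       const std::vector<double>& d, int n) {
  double s = 0.0;
  for (size_t i = 1; i < ord.size(); ++i) s += d[ord[i - 1] * n + ord[i]];
  return s;
}

// One first-improvement 2-opt pass (open path: only boundary edges change).
static bool two_opt_pass(std::vector<int>& ord, const std::vector<double>& d,
                         int n) {
  bool improved = false;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;
      double delta = 0.0;
      if (i > 0)
        delta += d[ord[i - 1] * n + ord[j]] - d[ord[i - 1] * n + ord[i]];
      if (j < n - 1)
        delta += d[ord[i] * n + ord[j + 1]] - d[ord[j] * n + ord[j + 1]];
      if (delta < -1e-10) {
        std::reverse(ord.begin() + i, ord.begin() + j + 1);
        improved = true;
      }
    }
  }
  return improved;
}

// One or-opt pass: relocate segments of length 1..3 (forward or reversed)
// to any other position, first improvement.
static bool or_opt_pass(std::vector<int>& ord, const std::vector<double>& d,
                        int n) {
  double cur_len = path_len(ord, d, n);
  for (int L = 1; L <= 3 && L < n; ++L) {
    for (int a = 0; a + L - 1 < n; ++a) {
      int b = a + L - 1;
      // remaining order with segment removed
      std::vector<int> rest;
      rest.reserve(n - L);
      for (int k = 0; k < n; ++k)
        if (k < a || k > b) rest.push_back(ord[k]);
      std::vector<int> seg(ord.begin() + a, ord.begin() + b + 1);
      std::vector<int> rseg(seg.rbegin(), seg.rend());
      for (size_t pos = 0; pos <= rest.size(); ++pos) {
        if ((int)pos == a) continue; // same placement, forward
        for (int rev = 0; rev < 2; ++rev) {
          std::vector<int> cand;
          cand.reserve(n);
          cand.insert(cand.end(), rest.begin(), rest.begin() + pos);
          const std::vector<int>& s = rev ? rseg : seg;
          cand.insert(cand.end(), s.begin(), s.end());
          cand.insert(cand.end(), rest.begin() + pos, rest.end());
          double len = path_len(cand, d, n);
          if (len < cur_len - 1e-10) {
            ord = cand;
            cur_len = len;
            return true;
          }
        }
      }
    }
  }
  return false;
}

// Best-of-all-starts nearest neighbor, each start refined by 2-opt and
// or-opt until no move improves.
// [[Rcpp::export(name = ".tsp_heuristic_cpp")]]
double tsp_heuristic_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) return 0.0;
  std::vector<double> d = dist_matrix(x, y);
  const double INF = std::numeric_limits<double>::infinity();
  double best = INF;
  for (int start = 0; start < n; ++start) {
    std::vector<int> ord;
    std::vector<bool> used(n, false);
    ord.reserve(n);
    ord.push_back(start);
    used[start] = true;
    for (int step = 1; step < n; ++step) {
      int cur = ord.back(), nxt = -1;
      double dn = INF;
      for (int k = 0; k < n; ++k) {
        if (used[k]) continue;
        if (d[cur * n + k] < dn) { dn = d[cur * n + k]; nxt = k; }
      }
      ord.push_back(nxt);
      used[nxt] = true;
    }
    bool improved = true;
    while (improved) {
      improved = two_opt_pass(ord, d, n);
      if (!improved) improved = or_opt_pass(ord, d, n);
    }
    best = std::min(best, path_len(ord, d, n));
  }
  return best;
}
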