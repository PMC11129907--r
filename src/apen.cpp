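#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Approximate entropy (Pincus): ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where
// Phi_m is the mean over the N-m+1 template vectors of log of the fraction
// of templates (self-matches included) within Chebyshev distance r.
//
// Fast path: a template pair (i, j) can only match if the scalar pair
// |x_i - x_j| <= r matches. Scalar matches are enumerated by sorting +
// two-pointer sweep and stored in an n x n bitset; template matches for
// m and m+1 are then read off with O(1) bit lookups per scalar match.

static double phi_from_counts(const std::vector<long>& cnt, int nt) {
  double s = 0.0;
  for (int i = 0; i < nt; ++i) s += std::log((double)cnt[i] / nt);
  return s / nt;
}

// plain O(n^2 m) fallback, also the shape of the test oracle
static double phi_direct(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nt = n - m + 1;
  std::vector<long> cnt(nt, 1);
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool within = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { within = false; break; }
      }
      if (within) { ++cnt[i]; ++cnt[j]; }
    }
  }
  return phi_from_counts(cnt, nt);
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) stop("series too short for approximate entropy");
  if (m < 1) stop("embedding dimension must be >= 1");

  // bitset memory grows as n^2 bits; beyond ~16k samples fall back
  if ((double)n * n > 2.7e8) {
    return phi_direct(x, m, r) - phi_direct(x, m + 1, r);
  }

  const size_t nb = ((size_t)n * n + 63) / 64;
  std::vector<uint64_t> B(nb, 0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  std::vector<std::pair<int, int> > pairs; // scalar matches, i < j
  pairs.reserve((size_t)n * 16);
  int lo = 0;
  for (int b = 0; b < n; ++b) {
    while (x[ord[b]] - x[ord[lo]] > r) ++lo;
    for (int a = lo; a < b; ++a) {
      int i = ord[a], j = ord[b];
      if (i > j) std::swap(i, j);
      const size_t bit = (size_t)i * n + j;
      B[bit >> 6] |= (uint64_t)1 << (bit & 63);
      pairs.push_back(std::make_pair(i, j));
    }
  }
  auto match = [&](int i, int j) -> bool {
    const size_t bit = (size_t)i * n + j;
    return (B[bit >> 6] >> (bit & 63)) & 1;
  };

  const int nt_m = n - m + 1, nt_m1 = n - m;
  std::vector<long> cnt_m(nt_m, 1), cnt_m1(nt_m1, 1); // self-matches
  for (size_t p = 0; p < pairs.size(); ++p) {
    const int i = pairs[p].first, j = pairs[p].second;
    if (j >= nt_m) continue;
    bool ok = true;
    for (int k = 1; k < m; ++k) {
      if (!match(i + k, j + k)) { ok = false; break; }
    }
    if (!ok) continue;
    ++cnt_m[i]; ++cnt_m[j];
    if (j < nt_m1 && match(i + m, j + m)) { ++cnt_m1[i]; ++cnt_m1[j]; }
  }
  return phi_from_counts(cnt_m, nt_m) - phi_from_counts(cnt_m1, nt_m1);
}
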