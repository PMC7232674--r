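// Exact acyclic assembly by subset dynamic programming.
//
// Given, for every node v, a list of candidate families (parent-set bitmask
// over the node indices, local BIC), find the acyclic assignment of one
// family per node maximizing the summed BIC:
//   best(S) = max over sinks v in S of best(S \ v) + g_v(S \ v)
// where g_v(A) = max bic of a family of v with parents inside A, computed
// for all A at once by a subset zeta transform.  Exponential in p; callers
// enforce p <= 20.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
List exact_dp_cpp(int p, List fam_masks, List fam_bics) {
  const size_t nS = size_t(1) << p;
  const double NEG = -std::numeric_limits<double>::infinity();

  // g[v][A]: best family bic of node v with parent mask contained in A
  std::vector<std::vector<double>> g(p);
  for (int v = 0; v < p; ++v) {
    g[v].assign(nS, NEG);
    IntegerVector masks = fam_masks[v];
    NumericVector bics = fam_bics[v];
    for (int j = 0; j < masks.size(); ++j) {
      size_t m = size_t(masks[j]);
      if (bics[j] > g[v][m]) g[v][m] = bics[j];
    }
    for (int b = 0; b < p; ++b) {
      const size_t bit = size_t(1) << b;
      for (size_t S = 0; S < nS; ++S)
        if (S & bit) {
          double alt = g[v][S ^ bit];
          if (alt > g[v][S]) g[v][S] = alt;
        }
    }
  }

  std::vector<double> best(nS, NEG);
  std::vector<signed char> choice(nS, -1);
  best[0] = 0.0;
  for (size_t S = 1; S < nS; ++S) {
    for (int v = 0; v < p; ++v) {
      const size_t bit = size_t(1) << v;
      if (!(S & bit)) continue;
      const size_t A = S ^ bit;
      if (best[A] == NEG || g[v][A] == NEG) continue;
      double val = best[A] + g[v][A];
      if (val > best[S]) { // strict: ties keep the smallest sink index
        best[S] = val;
        choice[S] = (signed char)v;
      }
    }
  }

  // backtrack: recover the sink sequence and, per node, the first family
  // (in the given rank order) achieving g_v(allowed)
  IntegerVector sel(p, NA_INTEGER);
  size_t S = nS - 1;
  while (S > 0) {
    int v = choice[S];
    if (v < 0) break; // unreachable with finite family scores
    const size_t A = S ^ (size_t(1) << v);
    IntegerVector masks = fam_masks[v];
    NumericVector bics = fam_bics[v];
    for (int j = 0; j < masks.size(); ++j) {
      size_t m = size_t(masks[j]);
      if ((m & A) == m && bics[j] == g[v][A]) { sel[v] = j + 1; break; }
    }
    S = A;
  }
  return List::create(_["selection"] = sel, _["score"] = best[nS - 1]);
}
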