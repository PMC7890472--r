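#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming core for step-pattern DTW with both endpoints
// anchored. The pattern is passed as a flat matrix with rows
// (chain, di, dj, weight); weight -1 marks the start-cell offset of a
// production, the remaining rows of the chain weight the local distance
// at cells (i - di, j - dj), ending at (0, 0). Productions are evaluated
// in the given row order and ties are kept on the earlier production, so
// ordering the diagonal production first makes tie-breaking
// diagonal-first and the output deterministic.


// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericMatrix x, NumericMatrix y, NumericMatrix pat,
              int window_size) {
  const int n = x.nrow(), m = y.nrow();
  const double inf = std::numeric_limits<double>::infinity();

  // precompute the local distance matrix once; productions revisit cells
  std::vector<double> dloc((size_t)n * m);
  {
    const int d = x.ncol();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          const double diff = x(i, k) - y(j, k);
          s += diff * diff;
        }
        dloc[(size_t)i * m + j] = std::sqrt(s);
      }
  }

  // unpack productions
  std::vector<int> chain_start, chain_len;
  {
    int r = 0;
    while (r < pat.nrow()) {
      chain_start.push_back(r);
      int len = 1;
      while (r + len < pat.nrow() && pat(r + len, 3) >= 0) ++len;
      chain_len.push_back(len);
      r += len;
    }
  }
  const int nprod = chain_start.size();
  const int npr = pat.nrow();
  std::vector<int> pdi(npr), pdj(npr);
  std::vector<double> pw(npr);
  for (int r = 0; r < npr; ++r) {
    pdi[r] = (int)pat(r, 1); pdj[r] = (int)pat(r, 2); pw[r] = pat(r, 3);
  }

  NumericMatrix g(n, m);
  IntegerMatrix from(n, m);
  std::fill(g.begin(), g.end(), inf);
  std::fill(from.begin(), from.end(), -1);
  g(0, 0) = dloc[0];

  const bool use_win = window_size >= 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == 0 && j == 0) continue;
      if (use_win && std::abs(i - j) > window_size &&
          !(i == n - 1 && j == m - 1)) continue;
      double best = inf;
      int bestp = -1;
      for (int p = 0; p < nprod; ++p) {
        const int r0 = chain_start[p];
        const int pi = i - pdi[r0];
        const int pj = j - pdj[r0];
        if (pi < 0 || pj < 0) continue;
        const double base = g(pi, pj);
        if (!std::isfinite(base)) continue;
        double c = base;
        for (int s = 1; s < chain_len[p]; ++s) {
          const int r = r0 + s;
          const double w = pw[r];
          if (w != 0.0)
            c += w * dloc[(size_t)(i - pdi[r]) * m + (j - pdj[r])];
        }
        if (c < best) { best = c; bestp = p; }
      }
      g(i, j) = best;
      from(i, j) = bestp;
    }
  }

  const double acc = g(n - 1, m - 1);
  if (!std::isfinite(acc)) {
    return List::create(_["feasible"] = false);
  }

  // backtrack, collecting every cell visited by the chosen chains
  std::vector<int> pi_rev, pj_rev;
  int i = n - 1, j = m - 1;
  while (!(i == 0 && j == 0)) {
    const int p = from(i, j);
    const int r0 = chain_start[p];
    // chain rows r0+1 .. r0+len-1 give cells from farthest to (0,0)
    for (int s = chain_len[p] - 1; s >= 1; --s) {
      pi_rev.push_back(i - pdi[r0 + s]);
      pj_rev.push_back(j - pdj[r0 + s]);
    }
    i -= pdi[r0];
    j -= pdj[r0];
  }
  pi_rev.push_back(0);
  pj_rev.push_back(0);

  const int plen = pi_rev.size();
  IntegerVector ip(plen), jp(plen);
  for (int k = 0; k < plen; ++k) {
    ip[k] = pi_rev[plen - 1 - k] + 1;  // 1-based
    jp[k] = pj_rev[plen - 1 - k] + 1;
  }

  return List::create(_["feasible"] = true,
                      _["accumulated_cost"] = acc,
                      _["index1"] = ip,
                      _["index2"] = jp);
}

// first-order autoregressive recursion y[t] = x[t] + a * y[t-1]
// [[Rcpp::export(name = ".ar1_filter")]]
NumericVector ar1_filter(NumericVector x, double a) {
  const int n = x.size();
  NumericVector y(n);
  double prev = 0.0;
  for (int t = 0; t < n; ++t) {
    prev = x[t] + a * prev;
    y[t] = prev;
  }
  return y;
}
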