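#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <numeric>
using namespace Rcpp;

// statistic codes: 1 = DM, 2 = CvM, 3 = maxLM
// Both entry points use R's RNG (norm_rand / unif_rand), so results are
// reproducible from set.seed() on the R side and match draws made in R
// in the same order.

// Simulate n_sim independent k-dimensional Brownian bridges on the grid
// i/grid_n (i = 1..grid_n) and return the chosen statistic of each draw.
// i_lo/i_hi bound the maxLM scan (1-based grid indices).
// [[Rcpp::export]]
NumericVector bridge_stat_reference_cpp(int n_sim, int grid_n, int k,
                                        int stat_code, int i_lo, int i_hi) {
  NumericVector out(n_sim);
  std::vector<double> w(grid_n);
  std::vector<double> rowss(grid_n);
  const double sd = 1.0 / std::sqrt((double)grid_n);

  for (int s = 0; s < n_sim; ++s) {
    std::fill(rowss.begin(), rowss.end(), 0.0);
    double dm = 0.0;
    for (int j = 0; j < k; ++j) {
      double c = 0.0;
      for (int i = 0; i < grid_n; ++i) {
        c += norm_rand() * sd;
        w[i] = c;
      }
      const double wn = w[grid_n - 1];
      for (int i = 0; i < grid_n; ++i) {
        const double t = (double)(i + 1) / grid_n;
        const double b = w[i] - t * wn;
        rowss[i] += b * b;
        if (stat_code == 1 && i < grid_n - 1) {
          const double a = std::fabs(b);
          if (a > dm) dm = a;
        }
      }
    }
    if (stat_code == 1) {
      out[s] = dm;
    } else if (stat_code == 2) {
      double tot = 0.0;
      for (int i = 0; i < grid_n; ++i) tot += rowss[i];
      out[s] = tot / grid_n;
    } else {
      double m = 0.0;
      for (int i = i_lo; i <= i_hi; ++i) {
        const double t = (double)i / grid_n;
        const double v = rowss[i - 1] / (t * (1.0 - t));
        if (v > m) m = v;
      }
      out[s] = m;
    }
  }
  return out;
}

static double stat_of_permuted(const double* U, int n, int k,
                               const std::vector<int>& idx,
                               int stat_code, int i_lo, int i_hi,
                               std::vector<double>& csum) {
  const double inv_sqrt_n = 1.0 / std::sqrt((double)n);
  std::fill(csum.begin(), csum.end(), 0.0);
  double dm = 0.0, cvm = 0.0, mlm = 0.0;
  for (int i = 0; i < n; ++i) {
    const int r = idx[i];
    double ss = 0.0;
    for (int j = 0; j < k; ++j) {
      csum[j] += U[r + (size_t)j * n] * inv_sqrt_n;
      const double c = csum[j];
      ss += c * c;
      if (stat_code == 1 && i < n - 1) {
        const double a = std::fabs(c);
        if (a > dm) dm = a;
      }
    }
    if (stat_code == 2) cvm += ss;
    if (stat_code == 3 && (i + 1) >= i_lo && (i + 1) <= i_hi) {
      const double t = (double)(i + 1) / n;
      const double v = ss / (t * (1.0 - t));
      if (v > mlm) mlm = v;
    }
  }
  if (stat_code == 1) return dm;
  if (stat_code == 2) return cvm / n;
  return mlm;
}

// Statistics of the fluctuation process rebuilt from n_perm uniform
// random permutations of the rows of U (the v-ordered, decorrelated
// score matrix). Fisher-Yates with unif_rand(), so a fixed R seed fixes
// the permutation sequence.
// [[Rcpp::export]]
NumericVector perm_stat_sample_cpp(NumericMatrix U, int n_perm,
                                   int stat_code, int i_lo, int i_hi) {
  const int n = U.nrow(), k = U.ncol();
  NumericVector out(n_perm);
  std::vector<int> idx(n);
  std::vector<double> csum(k);
  for (int s = 0; s < n_perm; ++s) {
    std::iota(idx.begin(), idx.end(), 0);
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    out[s] = stat_of_permuted(REAL(U), n, k, idx, stat_code, i_lo, i_hi, csum);
  }
  return out;
}
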