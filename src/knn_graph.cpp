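#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sum over all points of the p-th power Euclidean distance to each k-th
// nearest neighbor, k in S.  pts is a flat row-major buffer (point-major:
// pts[i*d + c]).  Brute-force O(n^2 d); n stays small enough in practice
// (bins of tens to hundreds of profiles, calibration at n = 10,000).
static double lp_sum_flat(const std::vector<double>& pts, int n, int d,
                          const std::vector<int>& S, double p) {
  int kmax = 0;
  for (size_t s = 0; s < S.size(); ++s) kmax = std::max(kmax, S[s]);
  std::vector<double> d2(n - 1);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = &pts[(size_t)i * d];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* xj = &pts[(size_t)j * d];
      double acc = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = xi[c] - xj[c];
        acc += diff * diff;
      }
      d2[m++] = acc;
    }
    std::partial_sort(d2.begin(), d2.begin() + kmax, d2.begin() + m);
    for (size_t s = 0; s < S.size(); ++s) {
      double dist2 = d2[S[s] - 1];
      total += (dist2 > 0.0) ? std::pow(std::sqrt(dist2), p) : 0.0;
    }
  }
  return total;
}

// Empirical copula transform of the flat point buffer in place:
// each coordinate replaced by (maximum rank)/n within its column.
static void copula_flat(std::vector<double>& pts, int n, int d) {
  std::vector<double> col(n), sorted(n);
  for (int c = 0; c < d; ++c) {
    for (int i = 0; i < n; ++i) col[i] = pts[(size_t)i * d + c];
    sorted = col;
    std::sort(sorted.begin(), sorted.end());
    for (int i = 0; i < n; ++i) {
      int r = (int)(std::upper_bound(sorted.begin(), sorted.end(), col[i]) -
                    sorted.begin());
      pts[(size_t)i * d + c] = (double)r / n;
    }
  }
}

// [[Rcpp::export]]
double lp_knn_sum_cpp(NumericMatrix x, IntegerVector neighbor_set, double p) {
  int n = x.nrow(), d = x.ncol();
  std::vector<int> S(neighbor_set.begin(), neighbor_set.end());
  std::vector<double> pts((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) pts[(size_t)i * d + c] = x(i, c);
  return lp_sum_flat(pts, n, d, S, p);
}

// [[Rcpp::export]]
NumericMatrix copula_transform_cpp(NumericMatrix x) {
  int n = x.nrow(), d = x.ncol();
  std::vector<double> pts((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) pts[(size_t)i * d + c] = x(i, c);
  copula_flat(pts, n, d);
  NumericMatrix z(n, d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) z(i, c) = pts[(size_t)i * d + c];
  return z;
}

// Null distribution of Delta-I for one modulator: each trial draws d random
// gene columns (shared by both bins), copula-transforms each bin's submatrix
// and evaluates I = coef * (log Lp - log_c) per bin, coef = 1/(alpha - 1).
// high/low are samples x genes matrices over the same gene columns.
// Uses R's RNG (honors set.seed on the R side).
// [[Rcpp::export]]
NumericVector perm_null_delta_cpp(NumericMatrix high, NumericMatrix low,
                                  int d, int L, IntegerVector neighbor_set,
                                  double p, double coef, double log_c_high,
                                  double log_c_low) {
  int nh = high.nrow(), nl = low.nrow(), G = high.ncol();
  std::vector<int> S(neighbor_set.begin(), neighbor_set.end());
  NumericVector out(L);
  std::vector<double> ph((size_t)nh * d), pl((size_t)nl * d);
  for (int t = 0; t < L; ++t) {
    IntegerVector pick = sample(G, d, false);  // 1-based column indices
    for (int c = 0; c < d; ++c) {
      int g = pick[c] - 1;
      for (int i = 0; i < nh; ++i) ph[(size_t)i * d + c] = high(i, g);
      for (int i = 0; i < nl; ++i) pl[(size_t)i * d + c] = low(i, g);
    }
    copula_flat(ph, nh, d);
    copula_flat(pl, nl, d);
    double lph = lp_sum_flat(ph, nh, d, S, p);
    double lpl = lp_sum_flat(pl, nl, d, S, p);
    if (lph <= 0.0 || lpl <= 0.0) {
      out[t] = NA_REAL;
      continue;
    }
    double ih = coef * (std::log(lph) - log_c_high);
    double il = coef * (std::log(lpl) - log_c_low);
    out[t] = ih - il;
  }
  return out;
}
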