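#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of the first n entries of buf (buf is scratch, reordered in place).
static double med_inplace(std::vector<double> &buf, int n) {
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double m = buf[h];
  if (n % 2 == 0) {
    // lower middle = max of the first half after partition
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

//' Per-gene two-group statistics over a set of label permutations.
//'
//' Computes, for every gene and every column of `perms`, the Welch t
//' statistic (A minus B), the tie-corrected standardized rank-sum z of
//' group A, and the difference of group medians (A minus B).
//'
//' @param x numeric matrix, genes x samples.
//' @param ranks per-gene within-row ranks of `x` (average ranks for ties),
//'   same dimensions as `x`.
//' @param w_var per-gene variance of the group-A rank sum under the null,
//'   already tie-corrected; length = number of genes.
//' @param perms integer matrix, samples x n_perm: each column is a 0-based
//'   permutation of the sample indices; the first `n1` rows of a column are
//'   the samples assigned to group A.
//' @param n1 number of samples in group A.
//' @return list of three genes x n_perm matrices: `t_stat`, `ranksum_z`,
//'   `lmr`.
//' @keywords internal
// [[Rcpp::export(name = ".perm_group_stats_cpp")]]
List perm_group_stats_cpp(NumericMatrix x, NumericMatrix ranks,
                          NumericVector w_var, IntegerMatrix perms, int n1) {
  const int G = x.nrow(), S = x.ncol(), P = perms.ncol();
  const int n2 = S - n1;
  if (n1 < 2 || n2 < 2) stop("each group must have at least 2 samples");
  if (perms.nrow() != S) stop("permutation matrix must have one row per sample");

  NumericMatrix t_out(G, P), z_out(G, P), l_out(G, P);
  std::vector<double> bufA((size_t)n1), bufB((size_t)n2);
  const double ew = n1 * (S + 1) / 2.0;

  for (int p = 0; p < P; ++p) {
    const int *idx = &perms(0, p);
    for (int g = 0; g < G; ++g) {
      double sA = 0.0, qA = 0.0, sB = 0.0, qB = 0.0, w = 0.0;
      for (int i = 0; i < n1; ++i) {
        const int c = idx[i];
        const double v = x(g, c);
        sA += v; qA += v * v; w += ranks(g, c);
        bufA[(size_t)i] = v;
      }
      for (int i = n1; i < S; ++i) {
        const int c = idx[i];
        const double v = x(g, c);
        sB += v; qB += v * v;
        bufB[(size_t)(i - n1)] = v;
      }
      const double mA = sA / n1, mB = sB / n2;
      const double vA = (qA - sA * mA) / (n1 - 1);
      const double vB = (qB - sB * mB) / (n2 - 1);
      const double den = std::sqrt((vA > 0 ? vA : 0) / n1 +
                                   (vB > 0 ? vB : 0) / n2);
      t_out(g, p) = den > 0 ? (mA - mB) / den : 0.0;
      z_out(g, p) = w_var[g] > 0 ? (w - ew) / std::sqrt(w_var[g]) : 0.0;
      l_out(g, p) = med_inplace(bufA, n1) - med_inplace(bufB, n2);
    }
  }
  return List::create(_["t_stat"] = t_out, _["ranksum_z"] = z_out,
                      _["lmr"] = l_out);
}
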