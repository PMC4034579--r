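#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Center--surround dissimilarity sums.
//
// feat: q x n matrix (one COLUMN per patch, transposed for cache locality),
// cent: 2 x n matrix of patch centers.
// Returns a 2 x n matrix: row 0 holds sum_{j != i} ||f_i-f_j||_1/(1+dist_ij),
// row 1 holds the weight mass sum_{j != i} 1/(1+dist_ij).  The caller turns
// these into count-averaged or weight-averaged scores.
//
// [[Rcpp::export(name = ".csd_sums_cpp")]]
NumericMatrix csd_sums_cpp(NumericMatrix feat, NumericMatrix cent) {
  const int q = feat.nrow(), n = feat.ncol();
  NumericMatrix out(2, n);
  for (int i = 0; i < n; ++i) {
    const double *fi = &feat(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double *fj = &feat(0, j);
      double l1 = 0.0;
      for (int k = 0; k < q; ++k) l1 += std::fabs(fi[k] - fj[k]);
      const double dr = cent(0, i) - cent(0, j);
      const double dc = cent(1, i) - cent(1, j);
      const double w = 1.0 / (1.0 + std::sqrt(dr * dr + dc * dc));
      const double d = l1 * w;
      out(0, i) += d;
      out(0, j) += d;
      out(1, i) += w;
      out(1, j) += w;
    }
  }
  return out;
}
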