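#include <RcppArmadillo.h>
#include "sh.h"
// [[Rcpp::depends(RcppArmadillo)]]

// Matrix of real even-degree SH basis values: one row per direction.
// [[Rcpp::export]]
arma::mat sh_basis_cpp(const arma::mat& dirs, int lmax) {
  if (lmax < 0 || lmax > SH_LMAX_CAP || lmax % 2 != 0)
    Rcpp::stop("lmax must be even and between 0 and %d", SH_LMAX_CAP);
  const int n = dirs.n_rows;
  const int nc = sh_ncoef(lmax);
  arma::mat B(n, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < n; ++i) {
    sh_eval(lmax, dirs(i, 0), dirs(i, 1), dirs(i, 2), row.data());
    for (int j = 0; j < nc; ++j) B(i, j) = row[j];
  }
  return B;
}
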