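#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Constrained spherical deconvolution, one voxel per row of S.
//
// S      nvox x ndir matrix of b0-normalized DW signals
// C      ndir x ncoef forward spherical-convolution matrix (basis at the
//        gradient directions scaled per degree by the response)
// B      ngrid x ncoef amplitude basis on a dense constraint grid
// ninit  number of leading coefficients used for the unconstrained
//        low-order initialisation (rank-safe with few directions)
// tau_frac  amplitude threshold as a fraction of the mean initial amplitude
// lambda    soft-constraint weight (scaled internally so data and penalty
//           rows are commensurate)
// maxit     cap on constraint iterations
//
// Returns nvox x ncoef FOD coefficients.
// [[Rcpp::export]]
arma::mat csd_solve_cpp(const arma::mat& S, const arma::mat& C,
                        const arma::mat& B, int ninit, double tau_frac,
                        double lambda, int maxit) {
  const int nvox = S.n_rows;
  const int ncoef = C.n_cols;
  const int ngrid = B.n_rows;
  if ((int)S.n_cols != (int)C.n_rows) Rcpp::stop("signal/convolution size mismatch");
  if (ninit < 1 || ninit > ncoef) Rcpp::stop("bad ninit");

  mat F(nvox, ncoef, fill::zeros);
  const mat Cinit = C.cols(0, ninit - 1);
  const mat Pinit = pinv(Cinit);
  const mat CtC = C.t() * C;
  // commensurate row scales for data and penalty blocks; the factor 5 sets
  // lambda = 1 to suppress negative lobes to within ~10% of the mean
  // amplitude on noiseless data
  const double lam = 5.0 * lambda *
      (norm(C, "fro") / std::sqrt((double)C.n_rows)) /
      (norm(B, "fro") / std::sqrt((double)ngrid));
  const double lam2 = lam * lam;

  for (int v = 0; v < nvox; ++v) {
    const vec s = S.row(v).t();
    if (!s.is_finite()) continue;
    vec f(ncoef, fill::zeros);
    f.subvec(0, ninit - 1) = Pinit * s;
    vec A = B * f;
    const double tau = tau_frac * std::max(mean(A), 0.0);
    const vec Cts = C.t() * s;
    uvec neg_prev;
    bool have_prev = false;
    for (int it = 0; it < maxit; ++it) {
      uvec neg = find(A < tau);
      if (have_prev && neg.n_elem == neg_prev.n_elem &&
          (neg.n_elem == 0 || all(neg == neg_prev)))
        break;
      neg_prev = neg; have_prev = true;
      mat M = CtC;
      if (neg.n_elem > 0) {
        const mat Bn = B.rows(neg);
        M += lam2 * (Bn.t() * Bn);
      }
      bool ok = solve(f, M, Cts, solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) { f = solve(M + 1e-8 * eye(ncoef, ncoef), Cts); }
      A = B * f;
    }
    F.row(v) = f.t();
  }
  return F;
}
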