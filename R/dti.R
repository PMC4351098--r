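#' Fit the diffusion tensor per voxel
#'
#' Weighted linear least-squares fit of the log-signal model
#' \eqn{\log S = \log s_0 - b g^T D g} (two WLS iterations, weights equal to
#' the squared predicted signal).  Non-positive intensities are replaced by
#' the smallest positive intensity in the voxel's series before the log, so
#' Rician noise floors never produce undefined logs.  Negative fitted
#' eigenvalues are clamped to zero before FA so FA stays in [0, 1].
#'
#' @param dwi a `dwi_volume`.
#' @param scheme a `gradient_scheme` (defaults to the one stored in `dwi`).
#' @param mask optional logical array restricting the fit.
#' @return object of class `tensor_field` with arrays `fa`, `adc` (mean
#'   diffusivity, mm^2/s), `evals` (x,y,z,3; descending), `evec1`
#'   (x,y,z,3; principal eigenvector), `tensor` (x,y,z,6; xx,yy,zz,xy,xz,yz),
#'   `s0`, and the fitting `mask`.
#' @export
fit_dti <- function(dwi, scheme = dwi$scheme, mask = NULL) {
  d <- dim(dwi$data)[1:3]
  nvol <- dim(dwi$data)[4]
  dw <- scheme_dw_index(scheme)
  if (length(dw) < 6 || nrow(unique(round(scheme$directions, 8))) < 6)
    stop("insufficient data: need >= 6 non-collinear diffusion directions")
  if (scheme$n_b0 < 1) stop("insufficient data: need >= 1 b0 volume")

  # design matrix rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz, -2b gygz]
  G <- matrix(0, nvol, 3)
  G[dw, ] <- scheme$directions
  b <- scheme$b_values
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])

  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- which(mask)
  flat <- matrix(dwi$data, prod(d), nvol)[vox, , drop = FALSE]
  # signal floor: smallest positive value in the voxel's own series
  floor_rep <- apply(flat, 1, function(r) {
    p <- r[r > 0]
    if (length(p)) min(p) else 1e-6
  })
  flat <- pmax(flat, floor_rep)
  Y <- log(flat)

  XtXi <- solve(crossprod(X))
  beta <- Y %*% X %*% XtXi            # OLS start, all voxels at once
  for (v in seq_along(vox)) {         # two WLS refinements per voxel
    bv <- beta[v, ]
    for (it in 1:2) {
      w <- exp(2 * (X %*% bv))        # squared predicted signal
      Xw <- X * as.vector(w)
      bv <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, Y[v, ])),
                     error = function(e) bv)
    }
    beta[v, ] <- bv
  }

  fa <- adc <- array(NA_real_, d)
  s0 <- array(NA_real_, d)
  evals <- array(NA_real_, c(d, 3))
  evec1 <- array(NA_real_, c(d, 3))
  tensor <- array(NA_real_, c(d, 6))
  n3 <- prod(d)
  for (v in seq_along(vox)) {
    bv <- beta[v, ]
    Dm <- matrix(c(bv[2], bv[5], bv[6],
                   bv[5], bv[3], bv[7],
                   bv[6], bv[7], bv[4]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)
    lam <- e$values                    # descending
    lam_c <- pmax(lam, 0)
    i <- vox[v]
    s0[i] <- exp(bv[1])
    adc[i] <- mean(lam)
    num <- sum((lam_c - mean(lam_c))^2)
    den <- sum(lam_c^2)
    fa[i] <- if (den > 0) min(1, sqrt(1.5 * num / den)) else 0
    evals[i + n3 * (0:2)] <- lam
    evec1[i + n3 * (0:2)] <- e$vectors[, 1]
    tensor[i + n3 * (0:5)] <- c(bv[2], bv[3], bv[4], bv[5], bv[6], bv[7])
  }
  structure(list(fa = fa, adc = adc, evals = evals, evec1 = evec1,
                 tensor = tensor, s0 = s0, mask = mask,
                 affine = dwi$affine),
            class = "tensor_field")
}

#' Fractional anisotropy of a set of eigenvalues
#'
#' Standard normalized eigenvalue-dispersion formula
#' \deqn{FA = \sqrt{3/2} \, \sqrt{\sum (\lambda_i - \bar\lambda)^2 / \sum \lambda_i^2}.}
#'
#' @param lambda numeric vector of 3 eigenvalues.
#' @return FA in [0, 1].
#' @export
fa_from_eigenvalues <- function(lambda) {
  lambda <- pmax(lambda, 0)
  den <- sum(lambda^2)
  if (den <= 0) return(0)
  min(1, sqrt(1.5 * sum((lambda - mean(lambda))^2) / den))
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor field: %d fitted voxels; FA median %.3f, ADC median %.2e mm^2/s\n",
              sum(x$mask), median(x$fa[x$mask], na.rm = TRUE),
              median(x$adc[x$mask], na.rm = TRUE)))
  invisible(x)
}
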