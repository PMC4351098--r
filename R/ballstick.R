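#' Fit the ball-and-stick model by MCMC
#'
#' Samples the posterior of the ball-and-stick signal model
#' \deqn{S = s_0 [ (1 - \sum_k f_k) e^{-b d} + \sum_k f_k e^{-b d (g^T v_k)^2} ]}
#' per voxel with Metropolis-within-Gibbs: component-wise random-walk
#' Metropolis updates for \eqn{s_0}, the shared diffusivity d, stick
#' fractions f and stick orientations (area prior on the sphere), and a
#' conjugate inverse-gamma Gibbs update for the Gaussian noise variance.
#' Proposal scales adapt during burn-in toward a 0.3-0.5 acceptance rate.
#' Deterministic for a fixed seed.
#'
#' @param dwi a `dwi_volume`.
#' @param scheme a `gradient_scheme`.
#' @param n_sticks number of stick compartments (1-3; default 2).
#' @param mcmc list with `burn_in`, `n_samples` (kept draws), `thin`.
#' @param seed integer seed.
#' @param mask logical array of voxels to fit.
#' @return object of class `ballstick_fit`: per-voxel posterior draws
#'   (`f` nvox x K x nsamp, `dir` nvox x K x 3 x nsamp, `d`, `s0`, `sigma`),
#'   posterior mean stick fractions `mean_f` (x, y, z, K), mean acceptance
#'   rates, `mask`, `affine`.
#' @export
ballstick_fit <- function(dwi, scheme = dwi$scheme, n_sticks = 2L,
                          mcmc = list(burn_in = 1000L, n_samples = 50L,
                                      thin = 25L),
                          seed = 1L, mask = NULL) {
  if (!n_sticks %in% 1:3) stop("invalid argument: n_sticks must be 1, 2 or 3")
  if (any(unlist(mcmc) <= 0)) stop("invalid argument: MCMC counts must be positive")
  d <- dim(dwi$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- which(mask)
  if (!length(vox)) stop("empty mask")
  n3 <- prod(d)
  nvol <- dim(dwi$data)[4]
  flat <- matrix(dwi$data, n3, nvol)[vox, , drop = FALSE]

  G <- matrix(0, nvol, 3)
  G[scheme_dw_index(scheme), ] <- scheme$directions
  res <- with_seed(seed, ballstick_mcmc_cpp(
    flat, G, scheme$b_values, as.integer(n_sticks),
    as.integer(mcmc$burn_in), as.integer(mcmc$n_samples),
    as.integer(mcmc$thin)))

  K <- n_sticks
  nsamp <- mcmc$n_samples
  mean_f <- array(0, c(d, K))
  mf <- apply(res$f, c(1, 2), mean)
  for (k in seq_len(K)) mean_f[vox + n3 * (k - 1)] <- mf[, k]
  structure(list(f = res$f, dir = res$dir, d = res$d, s0 = res$s0,
                 sigma = res$sigma, acceptance = res$acceptance,
                 mean_f = mean_f, n_sticks = K, n_samples = nsamp,
                 voxels = vox, mask = mask, affine = dwi$affine),
            class = "ballstick_fit")
}

#' Posterior summary of one ball-and-stick voxel
#'
#' @param fit a `ballstick_fit`.
#' @param voxel linear voxel index (into the full grid) or 3-vector of
#'   0-based voxel indices.
#' @return list with posterior mean fractions, mean dyadic orientations
#'   (principal eigenvector of the mean outer product, so antipodal draws
#'   do not cancel), mean diffusivity, and 90% credible intervals for f.
#' @export
ballstick_summary <- function(fit, voxel) {
  if (length(voxel) == 3)
    voxel <- 1 + voxel[1] + dim(fit$mask)[1] * (voxel[2] + dim(fit$mask)[2] * voxel[3])
  r <- match(voxel, fit$voxels)
  if (is.na(r)) stop("voxel not in the fitted mask")
  K <- fit$n_sticks; ns <- fit$n_samples
  f <- matrix(fit$f[r, , ], K, ns)
  mean_dir <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    dk <- t(matrix(fit$dir[r, k, , ], 3, ns))   # ns x 3 draws
    M <- crossprod(dk) / ns
    mean_dir[k, ] <- eigen(M, symmetric = TRUE)$vectors[, 1]
  }
  list(mean_f = rowMeans(f),
       ci90_f = t(apply(f, 1, quantile, probs = c(0.05, 0.95))),
       mean_dir = mean_dir,
       mean_d = mean(fit$d[r, ]),
       acceptance = fit$acceptance[r])
}

#' @export
print.ballstick_fit <- function(x, ...) {
  cat(sprintf("ball-and-stick fit: %d voxels, %d sticks, %d kept samples\n",
              length(x$voxels), x$n_sticks, x$n_samples))
  cat(sprintf("  mean MH acceptance: %.2f\n",
              mean(x$acceptance, na.rm = TRUE)))
  invisible(x)
}
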