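#' Estimate the single-fiber response function
#'
#' Selects high-anisotropy voxels (FA above `fa_cutoff`), rotates each
#' voxel's gradient directions so its principal eigenvector maps onto +z,
#' normalizes the signal by the voxel's b0, and fits zonal (m = 0) spherical
#' harmonics to the pooled aligned signals.  The zonal coefficients define
#' the axially symmetric response used by constrained spherical
#' deconvolution.
#'
#' @param dwi a `dwi_volume`.
#' @param scheme a `gradient_scheme`.
#' @param tensor a fitted `tensor_field` (for FA and eigenvectors).
#' @param fa_cutoff FA threshold selecting single-fiber voxels.
#' @param lmax maximum even harmonic order of the response.
#' @param max_voxels cap on the number of voxels pooled (highest FA first).
#' @return object of class `response_function`: zonal coefficients `rl`
#'   (one per even degree), `lmax`, `b_value`, `n_voxels`.
#' @export
estimate_response <- function(dwi, scheme = dwi$scheme, tensor,
                              fa_cutoff = 0.7, lmax = 6, max_voxels = 300L) {
  cand <- which(tensor$mask & !is.na(tensor$fa) & tensor$fa > fa_cutoff)
  if (length(cand) < 10)
    stop(sprintf("insufficient data: only %d voxels with FA > %g (need >= 10)",
                 length(cand), fa_cutoff))
  if (length(cand) > max_voxels)
    cand <- cand[order(tensor$fa[cand], decreasing = TRUE)[seq_len(max_voxels)]]

  d <- dim(dwi$data)[1:3]
  n3 <- prod(d)
  nvol <- dim(dwi$data)[4]
  flat <- matrix(dwi$data, n3, nvol)
  dw <- scheme_dw_index(scheme)
  b0i <- scheme_b0_index(scheme)
  g <- scheme$directions

  zs <- NULL; ss <- NULL
  for (i in cand) {
    e1 <- c(tensor$evec1[i], tensor$evec1[i + n3], tensor$evec1[i + 2 * n3])
    R <- rotation_between(e1, c(0, 0, 1))
    grot <- g %*% t(R)
    s0v <- mean(flat[i, b0i])
    if (!is.finite(s0v) || s0v <= 0) next
    zs <- rbind(zs, grot)
    ss <- c(ss, flat[i, dw] / s0v)
  }
  # zonal design: Y_l0(theta) at the reoriented directions
  zi <- sh_zonal_index(lmax)
  B <- sh_basis(zs, lmax)[, zi, drop = FALSE]
  rl <- as.vector(solve(crossprod(B), crossprod(B, ss)))
  if (rl[1] <= 0) stop("degenerate response: l = 0 coefficient must be positive")
  structure(list(rl = rl, lmax = lmax,
                 b_value = max(scheme$b_values), n_voxels = length(cand)),
            class = "response_function")
}

#' Signal amplitudes predicted by a response aligned with +z
#'
#' @param response a `response_function`.
#' @param dirs n x 3 unit directions.
#' @return predicted normalized signals.
#' @export
response_signal <- function(response, dirs) {
  zi <- sh_zonal_index(response$lmax)
  as.vector(sh_basis(dirs, response$lmax)[, zi, drop = FALSE] %*% response$rl)
}

# forward spherical-convolution matrix: SH basis at the gradient directions,
# scaled per degree by sqrt(4 pi / (2l + 1)) r_l
csd_forward_matrix <- function(response, dirs, lmax) {
  ls <- sh_degree(lmax)
  rl_all <- response$rl[match(ls, seq(0, response$lmax, by = 2))]
  rl_all[is.na(rl_all)] <- 0
  w <- sqrt(4 * pi / (2 * ls + 1)) * rl_all
  sh_basis(dirs, lmax) * rep(w, each = nrow(matrix(dirs, ncol = 3)))
}

#' Constrained spherical deconvolution
#'
#' Per voxel, deconvolves the single-fiber response from the b0-normalized
#' DW signal by linear least squares in the SH domain (spherical convolution
#' theorem), then applies the iterative soft non-negativity constraint:
#' FOD amplitudes on a dense direction grid falling below
#' `tau = tau_frac x mean initial amplitude` are penalized with weight
#' `lambda` and the system is re-solved until the constraint set is stable
#' (at most `max_iter` iterations).  Initialisation uses an unconstrained
#' low-order (lmax <= 4) fit, which is rank-safe at 30 directions.
#'
#' @param dwi a `dwi_volume`.
#' @param scheme a `gradient_scheme`.
#' @param response a `response_function` estimated at the scheme's b-value.
#' @param lmax maximum even harmonic order (even, <= 8; default 6).
#' @param mask logical array of voxels to fit (required; empty mask yields
#'   an empty field with a warning).
#' @param constraint_grid_n size of the dense constraint grid.
#' @param tau_frac,lambda,max_iter constraint parameters.
#' @return object of class `fod_field`: `coef` array (x, y, z, ncoef),
#'   `lmax`, `mask`, `affine`.
#' @export
csd_fit <- function(dwi, scheme = dwi$scheme, response, lmax = 6,
                    mask = NULL, constraint_grid_n = 300L, tau_frac = 0.1,
                    lambda = 1, max_iter = 50L) {
  if (lmax %% 2 != 0 || lmax > 8) stop("invalid argument: lmax must be even and <= 8")
  if (abs(response$b_value - max(scheme$b_values)) > 1e-6)
    stop("response was estimated at a different b-value than the scheme")
  d <- dim(dwi$data)[1:3]
  ncoef <- sh_ncoef(lmax)
  if (is.null(mask)) mask <- array(TRUE, d)
  vox <- which(mask)
  out <- array(0, c(d, ncoef))
  if (length(vox) == 0) {
    warning("empty mask: returning an empty FOD field")
    return(structure(list(coef = out, lmax = lmax, mask = mask,
                          affine = dwi$affine), class = "fod_field"))
  }
  n3 <- prod(d)
  nvol <- dim(dwi$data)[4]
  flat <- matrix(dwi$data, n3, nvol)
  dw <- scheme_dw_index(scheme)
  b0i <- scheme_b0_index(scheme)
  s0v <- rowMeans(flat[vox, b0i, drop = FALSE])
  S <- flat[vox, dw, drop = FALSE] / pmax(s0v, 1e-9)

  C <- csd_forward_matrix(response, scheme$directions, lmax)
  B <- sh_basis(sphere_grid(constraint_grid_n), lmax)
  ninit <- sh_ncoef(min(lmax, 4))
  if (ninit > length(dw)) ninit <- sh_ncoef(max(0, lmax - 2))
  ninit <- min(ninit, length(dw), ncoef)
  coefs <- csd_solve_cpp(S, C, B, as.integer(ninit), tau_frac, lambda,
                         as.integer(max_iter))
  for (cc in seq_len(ncoef)) out[vox + n3 * (cc - 1)] <- coefs[, cc]
  structure(list(coef = out, lmax = lmax, mask = mask, affine = dwi$affine),
            class = "fod_field")
}

#' FOD amplitudes of one voxel on a direction set
#'
#' @param coef SH coefficient vector.
#' @param dirs n x 3 directions.
#' @return amplitude vector.
#' @export
fod_amplitudes <- function(coef, dirs) {
  lmax <- sh_lmax_from_ncoef(length(coef))
  as.vector(sh_basis(dirs, lmax) %*% coef)
}

sh_lmax_from_ncoef <- function(nc) {
  for (l in seq(0, 12, by = 2)) if (sh_ncoef(l) == nc) return(l)
  stop("coefficient count does not match an even-degree basis")
}

#' Peaks of a fiber orientation distribution
#'
#' Finds local maxima of the FOD amplitude on a dense grid, refines each by
#' projected-gradient ascent on the sphere, merges antipodal/duplicate
#' peaks, and drops peaks below `min_relative_amplitude` times the global
#' maximum.
#'
#' @param coef SH coefficient vector of one voxel.
#' @param grid dense direction grid (>= 100 directions).
#' @param min_relative_amplitude relative amplitude cutoff.
#' @param merge_angle peaks closer than this (degrees, axial) are merged.
#' @return k x 3 matrix of unit peak orientations (strongest first), with
#'   attribute `amplitudes`; 0-row matrix if the FOD is empty.
#' @export
fod_peaks <- function(coef, grid = sphere_grid(300),
                      min_relative_amplitude = 0.1, merge_angle = 15) {
  if (nrow(grid) < 100) stop("invalid argument: grid must have >= 100 directions")
  if (all(abs(coef) < 1e-12))
    return(structure(matrix(0, 0, 3), amplitudes = numeric(0)))
  lmax <- sh_lmax_from_ncoef(length(coef))
  A <- as.vector(sh_basis(grid, lmax) %*% coef)
  # local maxima among grid neighbours
  nn <- 8L
  D <- abs(tcrossprod(grid))
  ord <- apply(D, 1, function(r) order(r, decreasing = TRUE)[2:(nn + 1)])
  is_max <- vapply(seq_len(nrow(grid)),
                   function(i) A[i] > 0 && all(A[i] >= A[ord[, i]]),
                   logical(1))
  cand <- which(is_max)
  if (!length(cand)) return(structure(matrix(0, 0, 3), amplitudes = numeric(0)))

  refine <- function(v) {
    amp <- function(u) sum(sh_basis(matrix(u, 1), lmax) * coef)
    step <- 0.05
    a <- amp(v)
    for (it in 1:50) {
      eps <- 1e-4
      gnum <- vapply(1:3, function(j) {
        e <- rep(0, 3); e[j] <- eps
        (amp(v + e) - amp(v - e)) / (2 * eps)
      }, numeric(1))
      gtan <- gnum - sum(gnum * v) * v
      if (sqrt(sum(gtan^2)) < 1e-8) break
      vn <- v + step * gtan
      vn <- vn / sqrt(sum(vn^2))
      an <- amp(vn)
      if (an > a) { v <- vn; a <- an } else step <- step / 2
      if (step < 1e-5) break
    }
    list(v = v, a = a)
  }
  ref <- lapply(cand, function(i) refine(grid[i, ]))
  peaks <- do.call(rbind, lapply(ref, `[[`, "v"))
  amps <- vapply(ref, `[[`, numeric(1), "a")
  o <- order(amps, decreasing = TRUE)
  peaks <- peaks[o, , drop = FALSE]; amps <- amps[o]
  keep_v <- NULL; keep_a <- numeric(0)
  cosm <- cos(merge_angle * pi / 180)
  for (i in seq_along(amps)) {
    if (is.null(keep_v) ||
        all(abs(keep_v %*% peaks[i, ]) < cosm)) {
      keep_v <- rbind(keep_v, peaks[i, ])
      keep_a <- c(keep_a, amps[i])
    }
  }
  sel <- keep_a >= min_relative_amplitude * keep_a[1] & keep_a > 0
  structure(keep_v[sel, , drop = FALSE], amplitudes = keep_a[sel])
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("response function (b = %g, lmax %d, %d voxels): rl = %s\n",
              x$b_value, x$lmax, x$n_voxels,
              paste(signif(x$rl, 3), collapse = ", ")))
  invisible(x)
}

#' @export
print.fod_field <- function(x, ...) {
  cat(sprintf("FOD field: lmax %d (%d coefficients), %d voxels\n",
              x$lmax, dim(x$coef)[4], sum(x$mask)))
  invisible(x)
}
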