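#' Real symmetric spherical harmonic basis
#'
#' Evaluates the real, even-degree (symmetric) orthonormal SH basis at a set
#' of unit directions.  Coefficient ordering: degrees l = 0, 2, ..., lmax
#' ascending; within each degree m = -l ... +l (sine terms for m < 0, the
#' zonal term at m = 0, cosine terms for m > 0).
#'
#' @param dirs n x 3 matrix of directions (normalized internally).
#' @param lmax maximum even harmonic order.
#' @return n x `sh_ncoef(lmax)` basis matrix.
#' @export
sh_basis <- function(dirs, lmax = 6) {
  dirs <- matrix(dirs, ncol = 3)
  sh_basis_cpp(normalize_rows(dirs), as.integer(lmax))
}

#' Number of even-degree SH coefficients
#'
#' @param lmax maximum even harmonic order.
#' @return `(lmax + 1) (lmax + 2) / 2`.
#' @export
sh_ncoef <- function(lmax) (lmax + 1) * (lmax + 2) / 2

# index (1-based) of the zonal (m = 0) coefficient of each even degree
sh_zonal_index <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  base <- cumsum(c(0, 2 * head(ls, -1) + 1))
  base + ls + 1
}

# per-coefficient degree labels
sh_degree <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

#' Quasi-uniform direction grid on the sphere
#'
#' Deterministic Fibonacci-spiral point set, used as the CSD constraint grid
#' and for peak finding.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_grid <- function(n = 300) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
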