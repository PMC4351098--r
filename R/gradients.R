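#' Generate a diffusion gradient scheme
#'
#' Builds an acquisition scheme of `n_b0` unweighted volumes followed by
#' `n_directions` diffusion-sensitizing directions at a single b-value.
#' Directions are spread over the half-sphere by minimizing the antipodally
#' symmetrized electrostatic (Coulomb) energy
#' \deqn{E = \sum_{i<j} 1/\|d_i - d_j\| + 1/\|d_i + d_j\|}
#' from a seeded random start, so the result is deterministic for a fixed
#' seed.  The default emulates a clinical 30-direction, b = 3000 s/mm^2
#' protocol.
#'
#' @param n_directions number of diffusion-weighted directions (>= 1).
#' @param b_value diffusion weighting in s/mm^2 (> 0).
#' @param n_b0 number of b = 0 volumes.
#' @param seed integer seed for the random initialisation.
#' @return an object of class `gradient_scheme`: list with `directions`
#'   (n x 3 unit rows), `b_values` (length `n_b0 + n_directions`, b0 first),
#'   and `n_b0`.
#' @export
generate_gradient_scheme <- function(n_directions, b_value = 3000,
                                     n_b0 = 1L, seed = 1L) {
  if (length(n_directions) != 1 || n_directions < 1)
    stop("invalid argument: n_directions must be >= 1")
  if (b_value <= 0) stop("invalid argument: b_value must be > 0")
  n <- as.integer(n_directions)
  dirs <- with_seed(seed, {
    x0 <- matrix(rnorm(3 * n), n, 3)
    if (n == 1) {
      normalize_rows(x0)
    } else {
      en <- function(p) {
        d <- normalize_rows(matrix(p, n, 3))
        electrostatic_energy(d)
      }
      fit <- optim(as.vector(x0), en, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10))
      normalize_rows(matrix(fit$par, n, 3))
    }
  })
  # orient each direction into the +z half-space for a canonical form
  flip <- dirs[, 3] < 0 | (dirs[, 3] == 0 & dirs[, 1] < 0)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  structure(
    list(directions = dirs,
         b_values = c(rep(0, n_b0), rep(b_value, n)),
         n_b0 = as.integer(n_b0)),
    class = "gradient_scheme")
}

#' Antipodally symmetrized electrostatic energy of a direction set
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @return scalar energy (lower = more uniform coverage of the half-sphere).
#' @export
electrostatic_energy <- function(dirs) {
  n <- nrow(dirs)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) {
    di <- dirs[i, ]
    for (j in (i + 1):n) {
      dm <- sqrt(sum((di - dirs[j, ])^2))
      dp <- sqrt(sum((di + dirs[j, ])^2))
      e <- e + 1 / max(dm, 1e-9) + 1 / max(dp, 1e-9)
    }
  }
  e
}

#' Minimum pairwise angle of a direction set
#'
#' Angles treat antipodal directions as identical (axial data).
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @return smallest pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(dirs) {
  g <- abs(tcrossprod(normalize_rows(dirs)))
  diag(g) <- 0
  acos(pmin(pmax(max(g), -1), 1)) * 180 / pi
}

#' Greedy energy-minimal subset of a gradient scheme
#'
#' Repeatedly removes the direction contributing most to the electrostatic
#' energy until `k` directions remain; used by the direction-subsampling
#' experiment to emulate acquiring fewer directions.
#'
#' @param scheme a `gradient_scheme`.
#' @param k target number of directions (6 <= k <= n).
#' @return a `gradient_scheme` with `k` directions plus an attribute
#'   `volume_index` giving the retained volume positions (b0 included).
#' @export
subset_gradient_scheme <- function(scheme, k) {
  n <- nrow(scheme$directions)
  if (k > n) stop("invalid argument: requested more directions than available")
  if (k < 6) stop("invalid argument: at least 6 directions required")
  keep <- seq_len(n)
  dirs <- scheme$directions
  while (length(keep) > k) {
    contrib <- vapply(seq_along(keep), function(i) {
      di <- dirs[keep[i], ]
      rest <- dirs[keep[-i], , drop = FALSE]
      dm <- sqrt(rowSums(sweep(rest, 2, di, `-`)^2))
      dp <- sqrt(rowSums(sweep(rest, 2, di, `+`)^2))
      sum(1 / pmax(dm, 1e-9) + 1 / pmax(dp, 1e-9))
    }, numeric(1))
    keep <- keep[-which.max(contrib)]
  }
  keep <- sort(keep)
  dw_idx <- scheme_dw_index(scheme)
  b0_idx <- scheme_b0_index(scheme)
  vol <- c(b0_idx, dw_idx[keep])
  out <- structure(
    list(directions = dirs[keep, , drop = FALSE],
         b_values = c(scheme$b_values[b0_idx], scheme$b_values[dw_idx[keep]]),
         n_b0 = length(b0_idx)),
    class = "gradient_scheme")
  attr(out, "volume_index") <- vol
  out
}

#' Write / read FSL-dialect gradient tables
#'
#' `bvecs` is written as 3 whitespace-separated rows of N entries (b0 columns
#' zero), `bvals` as a single row of N entries.
#'
#' @param scheme a `gradient_scheme`.
#' @param bvec_path,bval_path output/input file paths.
#' @return `read_fsl_gradients` returns a `gradient_scheme`.
#' @export
write_fsl_gradients <- function(scheme, bvec_path, bval_path) {
  nb0 <- scheme$n_b0
  vec <- rbind(matrix(0, nb0, 3), scheme$directions)
  writeLines(apply(t(vec), 1, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), bvec_path)
  writeLines(paste(formatC(scheme$b_values, format = "g", digits = 10),
                   collapse = " "), bval_path)
  invisible(c(bvec = bvec_path, bval = bval_path))
}

#' @rdname write_fsl_gradients
#' @export
read_fsl_gradients <- function(bvec_path, bval_path) {
  vec <- unname(t(as.matrix(utils::read.table(bvec_path))))
  bval <- as.numeric(utils::read.table(bval_path))
  dw <- bval > 50
  structure(list(directions = normalize_rows(vec[dw, , drop = FALSE]),
                 b_values = ifelse(dw, bval, 0),
                 n_b0 = sum(!dw),
                 dw_index = which(dw)),
            class = "gradient_scheme")
}

# volume indices of the diffusion-weighted subset (b0-first convention
# unless the scheme records an explicit layout)
scheme_dw_index <- function(scheme) {
  scheme$dw_index %||% (scheme$n_b0 + seq_len(nrow(scheme$directions)))
}

scheme_b0_index <- function(scheme) {
  setdiff(seq_along(scheme$b_values), scheme_dw_index(scheme))
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d directions at b = %g s/mm^2, %d b0 volume(s)\n",
              nrow(x$directions), max(x$b_values), x$n_b0))
  cat(sprintf("  minimum pairwise angle: %.1f deg\n",
              if (nrow(x$directions) > 1) min_pairwise_angle(x$directions) else NA))
  invisible(x)
}
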