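# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' Deterministic fan-out of one global seed into independent stage seeds, so
#' that any stage of the pipeline can be re-run in isolation and reproduce
#' its output.  All derived seeds stay below `.Machine$integer.max`.
#'
#' @param seed integer global seed.
#' @param stage integer stage identifier (any small non-negative integer).
#' @param subject integer subject/replicate index (default 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, subject = 0L) {
  s <- (as.double(seed %% 1e6) * 7919 + as.double(stage) * 104729 +
          as.double(subject) * 131) %% 2147483629
  as.integer(s) + 1L
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# unit-normalize rows of a matrix
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, .Machine$double.eps)
}

# angle in degrees between two direction vectors, antipodally symmetric if
# axial = TRUE
angle_deg <- function(a, b, axial = FALSE) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (axial) d <- abs(d)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

# rotation matrix mapping unit vector v onto unit vector w (Rodrigues)
rotation_between <- function(v, w) {
  v <- v / sqrt(sum(v^2)); w <- w / sqrt(sum(w^2))
  c_ <- sum(v * w)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * v) * v
    u <- u / sqrt(sum(u^2))
    return(2 * outer(u, u) - diag(3))
  }
  k <- c(v[2] * w[3] - v[3] * w[2],
         v[3] * w[1] - v[1] * w[3],
         v[1] * w[2] - v[2] * w[1])
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# world coordinates (n x 3) of 0-based voxel indices under a 4x4 affine
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# 0-based fractional voxel coordinates of world positions
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# linear (1-based) index of nearest voxels for world positions; NA outside
world_to_linear <- function(xyz, affine, dim3) {
  v <- round(world_to_voxel(xyz, affine))
  ok <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
    v[, 1] < dim3[1] & v[, 2] < dim3[2] & v[, 3] < dim3[3]
  out <- rep(NA_integer_, nrow(v))
  out[ok] <- 1L + as.integer(v[ok, 1] + dim3[1] * (v[ok, 2] + dim3[2] * v[ok, 3]))
  out
}

# separable Gaussian blur of a 3-D array (zero-padded borders)
gauss_blur3d <- function(arr, sigma_vox = 1, half_width = 4L) {
  off <- -half_width:half_width
  kern <- dnorm(off, sd = sigma_vox)
  kern <- kern / sum(kern)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    for (i in seq_along(off)) {
      o <- off[i]
      src <- pmin(pmax(seq_len(d[axis]) - o, 1L), d[axis])
      valid <- (seq_len(d[axis]) - o) >= 1L & (seq_len(d[axis]) - o) <= d[axis]
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- src
      shifted <- do.call(`[`, c(list(arr), idx))
      dim(shifted) <- d
      zap <- list(TRUE, TRUE, TRUE)
      zap[[axis]] <- !valid
      shifted <- do.call(`[<-`, c(list(shifted), zap, list(value = 0)))
      out <- out + kern[i] * shifted
    }
    arr <- out
  }
  arr
}

# binary dilation of a logical 3-D array by a Euclidean radius (in voxels)
dilate_mask <- function(mask, radius_vox) {
  r <- ceiling(radius_vox)
  off <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  off <- off[off$i^2 + off$j^2 + off$k^2 <= radius_vox^2, ]
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (n in seq_len(nrow(off))) {
    sh <- cbind(idx[, 1] + off$i[n], idx[, 2] + off$j[n], idx[, 3] + off$k[n])
    keep <- sh[, 1] >= 1 & sh[, 2] >= 1 & sh[, 3] >= 1 &
      sh[, 1] <= d[1] & sh[, 2] <= d[2] & sh[, 3] <= d[3]
    out[sh[keep, , drop = FALSE]] <- TRUE
  }
  out
}
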