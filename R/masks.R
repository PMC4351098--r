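#' Resample a scalar map onto a target grid under given affines
#'
#' Trilinear interpolation of `map` (with voxel-to-world affine
#' `map_affine`) at the voxel centers of the target grid; positions falling
#' outside the source field of view get 0.  Registration *estimation* is out
#' of scope — both affines are taken as given.
#'
#' @param map 3-D numeric array.
#' @param map_affine 4x4 voxel-to-world matrix of `map`.
#' @param target_shape target grid dimensions.
#' @param target_affine 4x4 voxel-to-world matrix of the target grid.
#' @return 3-D array with `target_shape` dimensions.
#' @export
resample_affine <- function(map, map_affine, target_shape, target_affine) {
  if (abs(det(map_affine)) < 1e-12 || abs(det(target_affine)) < 1e-12)
    stop("invalid argument: singular affine")
  d <- dim(map)
  ijk_t <- as.matrix(expand.grid(i = 0:(target_shape[1] - 1),
                                 j = 0:(target_shape[2] - 1),
                                 k = 0:(target_shape[3] - 1)))
  w <- voxel_to_world(ijk_t, target_affine)
  v <- world_to_voxel(w, map_affine)
  f0 <- floor(v)
  fr <- v - f0
  out <- numeric(nrow(v))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- f0[, 1] + di; jj <- f0[, 2] + dj; kk <- f0[, 3] + dk
    wt <- (if (di) fr[, 1] else 1 - fr[, 1]) *
          (if (dj) fr[, 2] else 1 - fr[, 2]) *
          (if (dk) fr[, 3] else 1 - fr[, 3])
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < d[1] & jj < d[2] & kk < d[3] & wt > 0
    lin <- 1 + ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok])
    out[ok] <- out[ok] + wt[ok] * map[lin]
  }
  array(out, target_shape)
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is retained iff its probability strictly exceeds `threshold`.
#' The default 0.1 mirrors thresholding a 10-brain probabilistic atlas so
#' that voxels belonging to more than one brain are kept.
#'
#' @param prob_map 3-D array with values in [0, 1].
#' @param threshold retention threshold (strict).
#' @return logical array.
#' @export
probability_to_mask <- function(prob_map, threshold = 0.1) {
  if (min(prob_map) < 0 || max(prob_map) > 1)
    stop("invalid argument: probabilities must lie in [0, 1]")
  m <- prob_map > threshold
  if (!any(m))
    stop(sprintf("empty mask: no voxel exceeds threshold %g", threshold))
  m
}

#' Build waypoint, exclusion and termination plane masks
#'
#' Follows the atlas-driven construction used for optic-radiation tracking:
#' the waypoint is the intersection of the tract (atlas) mask with the
#' single coronal slice nearest `waypoint_offset` mm posterior to the
#' temporal pole; the exclusion mask is the full coronal plane nearest
#' `exclusion_offset` mm posterior to the temporal pole, restricted to the
#' hemisphere containing the tract mask; the termination mask is the full
#' sagittal plane nearest `midline_x`.  "Posterior" means smaller world-y
#' (RAS+).
#'
#' @param or_mask logical array: the tract (atlas) mask.
#' @param affine 4x4 voxel-to-world matrix.
#' @param tp temporal-pole world coordinate (mm, length 3) or its y value.
#' @param waypoint_offset,exclusion_offset mm posterior to the TP.
#' @param midline_x sagittal plane position, world mm.
#' @return list of logical arrays `waypoint`, `exclusion`, `termination`,
#'   plus the chosen slice indices.
#' @export
make_planes <- function(or_mask, affine, tp, waypoint_offset = 60,
                        exclusion_offset = 20, midline_x = 0) {
  d <- dim(or_mask)
  tp_y <- if (length(tp) == 3) tp[2] else tp
  # voxel indices along each axis from world coordinates (axis-aligned grid)
  ys <- voxel_to_world(cbind(0, 0:(d[2] - 1), 0), affine)[, 2]
  xs <- voxel_to_world(cbind(0:(d[1] - 1), 0, 0), affine)[, 1]
  pick <- function(vals, target, what) {
    i <- which.min(abs(vals - target))
    if (abs(vals[i] - target) > max(diff(sort(vals))))
      stop(sprintf("invalid argument: %s plane (%.1f mm) outside grid", what,
                   target))
    i
  }
  jw <- pick(ys, tp_y - waypoint_offset, "waypoint")
  je <- pick(ys, tp_y - exclusion_offset, "exclusion")
  it <- pick(xs, midline_x, "termination")

  waypoint <- array(FALSE, d)
  waypoint[, jw, ] <- or_mask[, jw, ]
  if (!any(waypoint))
    stop("empty waypoint: tract mask does not reach the waypoint slice")

  # exclusion restricted to the hemisphere holding the tract mask
  cen_x <- mean(xs[which(or_mask, arr.ind = TRUE)[, 1]])
  same_side <- if (cen_x >= midline_x) xs >= midline_x else xs <= midline_x
  exclusion <- array(FALSE, d)
  exclusion[same_side, je, ] <- TRUE

  termination <- array(FALSE, d)
  termination[it, , ] <- TRUE
  list(waypoint = waypoint, exclusion = exclusion, termination = termination,
       waypoint_slice = jw - 1L, exclusion_slice = je - 1L,
       termination_slice = it - 1L)
}

#' FA-thresholded white-matter inclusion mask
#'
#' Voxels with FA strictly above `threshold`, optionally restricted to one
#' hemisphere (split at the sagittal plane `midline_x`).
#'
#' @param fa 3-D FA array (values in [0, 1]; NAs treated as 0).
#' @param affine 4x4 voxel-to-world matrix.
#' @param threshold FA threshold (default 0.1).
#' @param hemisphere one of "both", "left", "right" (left = x < midline,
#'   right = x > midline in RAS+).
#' @param midline_x sagittal split position, world mm.
#' @return logical array.
#' @export
make_inclusion_mask <- function(fa, affine, threshold = 0.1,
                                hemisphere = c("both", "left", "right"),
                                midline_x = 0) {
  hemisphere <- match.arg(hemisphere)
  fa0 <- fa
  fa0[is.na(fa0)] <- 0
  if (max(fa0) > 1 || min(fa0) < 0) stop("invalid argument: FA must be in [0, 1]")
  m <- fa0 > threshold
  if (hemisphere != "both") {
    d <- dim(fa)
    xs <- voxel_to_world(cbind(0:(d[1] - 1), 0, 0), affine)[, 1]
    keep <- if (hemisphere == "left") xs < midline_x else xs > midline_x
    m[!keep, , ] <- FALSE
  }
  if (!any(m)) stop("empty inclusion mask: no FA above threshold")
  m
}

#' Mean-b0 brain mask
#'
#' Standard pre-processing step: voxels whose mean unweighted signal exceeds
#' `frac` of the robust (99th percentile) maximum.  Separates object voxels
#' from the noise-only background of magnitude data.
#'
#' @param dwi a `dwi_volume`.
#' @param scheme a `gradient_scheme`.
#' @param frac fraction of the robust maximum.
#' @return logical array.
#' @export
brain_mask <- function(dwi, scheme = dwi$scheme, frac = 0.3) {
  b0i <- scheme_b0_index(scheme)
  d <- dim(dwi$data)[1:3]
  b0 <- apply(dwi$data[, , , b0i, drop = FALSE], 1:3, mean)
  thr <- frac * quantile(b0, 0.99)
  array(b0 > thr, d)
}
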