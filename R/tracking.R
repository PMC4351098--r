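#' Tracking parameters
#'
#' Defaults follow the emulated clinical protocol: 0.2 mm step length,
#' 0.3 mm radius-of-curvature cutoff and an FA threshold of 0.1 (the FA
#' threshold defines the inclusion mask).  The per-step turning cone derives
#' from the arc-chord relation
#' `max angle = 2 asin(step_length / (2 radius))` (about 38.9 degrees at
#' the defaults).  `streamlines_per_seed_voxel` defaults to the clinical
#' protocol's 5000; desk-scale runs override it (the pipeline default
#' config uses 100).
#'
#' @param streamlines_per_seed_voxel streamlines launched per seed voxel.
#' @param step_length mm.
#' @param min_radius_of_curvature mm.
#' @param fa_threshold inclusion-mask FA threshold.
#' @param max_length maximum streamline length, mm.
#' @param max_trials rejection-sampling cap per step.
#' @param amplitude_cutoff FOD amplitude cutoff for admissible directions,
#'   as a fraction of the voxel's peak amplitude; suppresses tracking along
#'   spurious deconvolution lobes and the noise floor.
#' @param seed integer seed.
#' @return list of class `tracking_params`.
#' @export
tracking_params <- function(streamlines_per_seed_voxel = 5000L,
                            step_length = 0.2,
                            min_radius_of_curvature = 0.3,
                            fa_threshold = 0.1,
                            max_length = 250,
                            max_trials = 500L,
                            amplitude_cutoff = 0.1,
                            seed = 1L) {
  if (step_length <= 0 || min_radius_of_curvature <= 0 ||
      streamlines_per_seed_voxel < 1)
    stop("invalid argument: tracking parameters must be positive")
  p <- as.list(environment())
  p$cone_angle <- cone_angle_deg(step_length, min_radius_of_curvature)
  class(p) <- "tracking_params"
  p
}

#' Maximum per-step turning angle for a curvature cutoff
#'
#' Arc-chord relation: a step of length s chords a circle of radius R with
#' turning angle `2 asin(s / (2R))` between consecutive chords.
#'
#' @param step_length chord (step) length, mm.
#' @param radius minimum radius of curvature, mm.
#' @return angle in degrees.
#' @export
cone_angle_deg <- function(step_length, radius) {
  x <- step_length / (2 * radius)
  if (x > 1) return(180)
  2 * asin(x) * 180 / pi
}

#' Propagate probabilistic streamlines
#'
#' Launches `streamlines_per_seed_voxel` streamlines from uniformly jittered
#' positions inside every seed voxel that lies in the inclusion mask, and
#' grows each bidirectionally with fixed-step Euler integration.  The
#' initial direction is sampled from the local model with no cone
#' restriction.  Per step, CSD tracking rejection-samples the trilinearly
#' interpolated FOD amplitude restricted to the curvature cone; ball-and-
#' stick tracking draws one posterior sample at the nearest voxel and
#' follows the admissible stick (posterior mean fraction >= `stick_f_min`)
#' closest to the incoming direction.  A streamline terminates on leaving
#' the inclusion mask, exceeding `max_length`, or when no admissible
#' direction is found within `max_trials`.
#'
#' @param model a `fod_field` or `ballstick_fit`.
#' @param seeds logical seed-mask array.
#' @param inclusion logical (FA-derived) inclusion-mask array.
#' @param params a [tracking_params()].
#' @param stick_f_min secondary-stick inclusion rule for ball-and-stick.
#' @return object of class `streamline_set`: `points` (list of n x 3 world-
#'   mm matrices), `status` per streamline ("candidate" until filtering),
#'   `initiated`, `n_seed_voxels`, `params`.
#' @export
propagate <- function(model, seeds, inclusion, params = tracking_params(),
                      stick_f_min = 0.05) {
  if (!any(seeds)) stop("empty seed mask")
  d <- dim(seeds)
  if (!identical(dim(inclusion), d)) stop("mask grids do not match")
  eligible <- seeds & inclusion
  n_skip <- sum(seeds) - sum(eligible)
  if (n_skip > 0)
    warning(sprintf("%d seed voxel(s) below the FA threshold produced no streamlines",
                    n_skip))
  if (!any(eligible)) stop("no seed voxel lies inside the inclusion mask")
  seed_ijk <- which(eligible, arr.ind = TRUE) - 1L
  storage.mode(seed_ijk) <- "integer"
  affine <- model$affine
  w2v <- solve(affine)
  cosc <- cos(params$cone_angle * pi / 180)

  res <- with_seed(params$seed, {
    if (inherits(model, "fod_field")) {
      ncoef <- dim(model$coef)[4]
      B <- sh_basis(sphere_grid(300), model$lmax)
      vox <- which(model$mask)
      vmax <- numeric(prod(d))
      if (length(vox)) {
        cf <- matrix(model$coef, prod(d), ncoef)[vox, , drop = FALSE]
        vmax[vox] <- apply(pmax(B %*% t(cf), 0), 2, max)
      }
      track_csd_cpp(as.numeric(model$coef), as.integer(d), model$lmax,
                    w2v, affine, as.integer(inclusion), vmax, seed_ijk,
                    as.integer(params$streamlines_per_seed_voxel),
                    params$step_length, cosc, params$max_length,
                    as.integer(params$max_trials),
                    params$amplitude_cutoff %||% 0.1)
    } else if (inherits(model, "ballstick_fit")) {
      nv <- prod(d)
      K <- model$n_sticks; ns <- model$n_samples
      # expand per-voxel posterior draws onto the full grid
      dirfull <- array(0, c(nv, K, 3, ns))
      dirfull[model$voxels, , , ] <- model$dir
      track_bs_cpp(as.numeric(dirfull), as.integer(d), K, ns,
                   as.numeric(model$mean_f), stick_f_min, w2v, affine,
                   as.integer(inclusion), seed_ijk,
                   as.integer(params$streamlines_per_seed_voxel),
                   params$step_length, cosc, params$max_length,
                   as.integer(params$max_trials))
    } else stop("model must be a fod_field or ballstick_fit")
  })
  structure(list(points = res$points,
                 status = rep("candidate", length(res$points)),
                 initiated = res$initiated,
                 n_seed_voxels = nrow(seed_ijk),
                 n_seed_voxels_skipped = n_skip,
                 affine = affine, dim = d, params = params),
            class = "streamline_set")
}

#' Filter streamlines by waypoint / target / exclusion / termination logic
#'
#' Each streamline is truncated at its first point falling in the
#' termination mask, then retained iff it visits at least one waypoint
#' voxel and at least one target voxel and no exclusion voxel.  Rejection
#' reasons are recorded per streamline.
#'
#' @param set a `streamline_set`.
#' @param waypoint,target,exclusion,termination logical arrays (any may be
#'   NULL to skip that test).
#' @return a `streamline_set` containing only retained streamlines, with
#'   `initiated`, `retained` counts and a `rejections` tally.
#' @export
filter_streamlines <- function(set, waypoint = NULL, target = NULL,
                               exclusion = NULL, termination = NULL) {
  d <- set$dim
  aff <- set$affine
  status <- character(length(set$points))
  kept <- vector("list", length(set$points))
  nk <- 0L
  for (i in seq_along(set$points)) {
    pts <- set$points[[i]]
    lin <- world_to_linear(pts, aff, d)
    if (!is.null(termination)) {
      hit <- which(!is.na(lin) & termination[pmax(lin, 1)])
      if (length(hit)) {
        pts <- pts[seq_len(hit[1]), , drop = FALSE]
        lin <- lin[seq_len(hit[1])]
      }
    }
    lin_ok <- lin[!is.na(lin)]
    if (!is.null(exclusion) && any(exclusion[lin_ok])) {
      status[i] <- "rejected:exclusion"
    } else if (!is.null(waypoint) && !any(waypoint[lin_ok])) {
      status[i] <- "rejected:no-waypoint"
    } else if (!is.null(target) && !any(target[lin_ok])) {
      status[i] <- "rejected:no-target"
    } else {
      status[i] <- "retained"
      nk <- nk + 1L
      kept[[nk]] <- pts
    }
  }
  rej <- table(status[status != "retained"])
  structure(list(points = kept[seq_len(nk)],
                 status = status,
                 initiated = set$initiated,
                 retained = nk,
                 rejections = rej,
                 n_seed_voxels = set$n_seed_voxels,
                 affine = aff, dim = d, params = set$params),
            class = "streamline_set")
}

#' Streamline-density image
#'
#' Voxel values are the fraction of retained streamlines visiting the voxel;
#' each streamline contributes at most once per voxel (binary visitation),
#' so values lie in [0, 1].
#'
#' @param set a filtered `streamline_set` with >= 1 retained streamline (or
#'   a plain list of point matrices).
#' @param dim3 grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return object of class `sdi`: `data` 3-D array, `n_streamlines`,
#'   `affine`.
#' @export
compute_sdi <- function(set, dim3 = set$dim, affine = set$affine) {
  pts <- if (inherits(set, "streamline_set")) set$points else set
  if (length(pts) < 1)
    stop("zero retained streamlines: review seeding/filtering parameters")
  counts <- numeric(prod(dim3))
  for (m in pts) {
    lin <- unique(world_to_linear(m, affine, dim3))
    lin <- lin[!is.na(lin)]
    counts[lin] <- counts[lin] + 1
  }
  structure(list(data = array(counts / length(pts), dim3),
                 n_streamlines = length(pts), affine = affine),
            class = "sdi")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline set: %d initiated", x$initiated))
  if (!is.null(x$retained)) {
    cat(sprintf(", %d retained\n", x$retained))
    if (length(x$rejections))
      cat("  rejections:",
          paste(names(x$rejections), as.integer(x$rejections), collapse = ", "),
          "\n")
  } else cat(sprintf(" (%d candidates, unfiltered)\n", length(x$points)))
  invisible(x)
}

#' @export
print.sdi <- function(x, ...) {
  cat(sprintf("SDI over %d streamlines: %d visited voxels, max density %.3f\n",
              x$n_streamlines, sum(x$data > 0), max(x$data)))
  invisible(x)
}
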