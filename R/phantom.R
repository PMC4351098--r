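#' Phantom configuration
#'
#' Parameters of the synthetic bent-fan tract phantom used as ground truth.
#' The geometry emulates, at reduced field of view, an optic radiation: a
#' fan of fibers leaves a seed region (lateral-geniculate analogue), runs
#' anteriorly, hooks sharply around a loop apex (Meyer's-loop analogue,
#' total turning 180 degrees) and returns posteriorly to a target region
#' (V1 analogue), optionally crossed by a straight second tract.  World
#' coordinates are NIfTI-style RAS+ (+y anterior), voxel indices 0-based,
#' and voxel (0,0,0) is centred at the world origin.
#'
#' All geometric values are artifact choices of this package (no public
#' phantom exists for this tract system); the acquisition-facing defaults
#' (2.5 mm voxels) follow the emulated clinical protocol.
#'
#' @param shape grid dimensions in voxels (x, y, z), at least 20 x 20 x 10.
#' @param voxel_size isotropic voxel edge in mm.
#' @param apex world-mm coordinate of the loop apex (the tract's true
#'   anterior tip).
#' @param loop_radius radius of the hairpin arc in mm.
#' @param seed_y,target_y world-y of the anterior limb base (seed end) and
#'   of the posterior fan edge (target end), mm.
#' @param tube_radius tract tube radius in mm.
#' @param fan_spread half-width in mm of the posterior fan (z direction);
#'   0 collapses the fan to a single tube.
#' @param fan_spread_x half-width of the posterior fan in x, mm.
#' @param n_fan number of fan curves.
#' @param crossing logical; add a straight crossing tract through the fan
#'   body.
#' @param crossing_y,crossing_z world position of the crossing tube axis, mm.
#' @param tp,op temporal-pole / occipital-pole analogue landmarks, world mm.
#' @param midline_x sagittal termination-plane position, world mm.
#' @param lambda_fiber fiber-compartment tensor eigenvalues, mm^2/s.
#' @param f_fiber intra-voxel fiber volume fraction in tract voxels.
#' @param d_iso isotropic (CSF-like) compartment diffusivity, mm^2/s.
#' @param d_background diffusivity of the isotropic tissue envelope, mm^2/s.
#' @param tissue_margin dilation radius (mm) of the tract system defining
#'   the tissue envelope; outside it there are no spins (background noise
#'   only).
#' @param seed_radius,target_radius radii (mm) of the seed / target masks.
#' @param prob_sigma Gaussian blur sigma (voxels) used to turn the binary
#'   truth into an atlas-style probability map.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(40L, 50L, 20L),
                           voxel_size = 2.5,
                           apex = c(60, 87.5, 25),
                           loop_radius = 7.5,
                           seed_y = 60,
                           target_y = 12.5,
                           tube_radius = 3,
                           fan_spread = 7.5,
                           fan_spread_x = 5,
                           n_fan = 9L,
                           crossing = TRUE,
                           crossing_y = 40,
                           crossing_z = 25,
                           tp = c(52.5, 115, 25),
                           op = c(60, 2.5, 25),
                           midline_x = 10,
                           lambda_fiber = c(1.7e-3, 0.3e-3, 0.3e-3),
                           f_fiber = 0.7,
                           d_iso = 3.0e-3,
                           d_background = 0.8e-3,
                           tissue_margin = 6,
                           seed_radius = 4,
                           target_radius = 7,
                           prob_sigma = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  cfg
}

# dense polyline samples (and tangents) of one fan curve, u in [-1, 1]
or_curve <- function(cfg, u, ds = 0.5) {
  r <- cfg$loop_radius
  ax <- cfg$apex[1]; az <- cfg$apex[3]
  yc <- cfg$apex[2] - r
  x_in <- ax - r
  # anterior limb: straight, +y
  y1 <- seq(cfg$seed_y, yc, by = ds)
  p1 <- cbind(x_in, y1, az)
  t1 <- matrix(rep(c(0, 1, 0), length(y1)), ncol = 3, byrow = TRUE)
  # hairpin arc over the apex, in the x-y plane
  arc_len <- pi * r
  s <- seq(0, 1, length.out = max(8, ceiling(arc_len / ds)))
  th <- pi * (1 - s)                    # pi -> 0
  p2 <- cbind(ax + r * cos(th), yc + r * sin(th), az)
  t2 <- cbind(r * sin(th), -r * cos(th), 0)  # d/ds direction (unnormalized)
  # posterior limb: straight, fanning out in z (and slightly x)
  x_out0 <- ax + r
  end <- c(x_out0 + u * cfg$fan_spread_x, cfg$target_y, az + u * cfg$fan_spread)
  L <- sqrt(sum((end - c(x_out0, yc, az))^2))
  s3 <- seq(0, 1, length.out = max(4, ceiling(L / ds)))
  p3 <- cbind(x_out0 + s3 * (end[1] - x_out0),
              yc + s3 * (end[2] - yc),
              az + s3 * (end[3] - az))
  t3 <- matrix(rep(end - c(x_out0, yc, az), length(s3)), ncol = 3, byrow = TRUE)
  pts <- rbind(p1, p2, p3)
  tan <- normalize_rows(rbind(t1, t2, t3))
  list(points = pts, tangents = tan,
       start = p1[1, ], end = p3[nrow(p3), ])
}

#' Build the synthetic optic-radiation phantom
#'
#' Constructs the ground-truth tract geometry, the per-voxel fiber field,
#' the seed/target masks, an atlas-style tract probability map (Gaussian
#' blur of the binary truth, max-normalized), landmarks, and the tissue
#' envelope.  The generator records the true anterior-tip world coordinate
#' (the configured apex) so downstream landmark errors can be measured
#' against construction truth.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed (reserved for randomized geometry variants;
#'   current geometry is deterministic).
#' @return object of class `phantom`: grid metadata (`shape`, `affine`,
#'   `voxel_size`), `fibers` (voxel index/orientation/fraction table),
#'   `iso_fraction` and `iso_diffusivity` arrays, masks (`tract_mask`,
#'   `seed_mask`, `target_mask`, `tissue_mask`), `tract_probability_map`,
#'   and `landmarks` (tp, op, apex, world mm).
#' @export
build_or_phantom <- function(config = phantom_config(), seed = 1L) {
  cfg <- config
  if (any(cfg$shape < c(20, 20, 10)))
    stop("invalid argument: grid must be at least 20 x 20 x 10 voxels")
  affine <- diag(c(rep(cfg$voxel_size, 3), 1))
  extent <- (cfg$shape - 1) * cfg$voxel_size
  inside <- function(p) all(p >= 0) && all(p <= extent)
  if (!inside(cfg$apex)) stop("invalid argument: loop apex outside grid")
  if (!inside(cfg$tp) || !inside(cfg$op))
    stop("invalid argument: landmarks must lie inside the grid")

  d <- cfg$shape
  nvox <- prod(d)
  centers <- voxel_to_world(
    as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))),
    affine)

  us <- if (cfg$n_fan == 1) 0 else seq(-1, 1, length.out = cfg$n_fan)
  curves <- lapply(us, function(u) or_curve(cfg, u))
  allpts <- do.call(rbind, lapply(curves, `[[`, "points"))
  alltan <- do.call(rbind, lapply(curves, `[[`, "tangents"))

  # nearest curve sample per voxel (restricted to a bounding box for speed)
  lo <- apply(allpts, 2, min) - cfg$tube_radius - 1
  hi <- apply(allpts, 2, max) + cfg$tube_radius + 1
  cand <- which(centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
                centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
                centers[, 3] >= lo[3] & centers[, 3] <= hi[3])
  tract <- array(FALSE, d)
  fib_idx <- integer(0); fib_dir <- NULL; fib_frac <- numeric(0)
  if (length(cand)) {
    cc <- centers[cand, , drop = FALSE]
    # chunked nearest-neighbour search
    nearest_d2 <- rep(Inf, nrow(cc)); nearest_i <- rep(1L, nrow(cc))
    chunk <- 2000L
    for (s in seq(1, nrow(allpts), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(allpts))
      block <- allpts[s:e, , drop = FALSE]
      d2 <- outer(rowSums(cc^2), rep(1, nrow(block))) -
        2 * cc %*% t(block) +
        outer(rep(1, nrow(cc)), rowSums(block^2))
      mi <- max.col(-d2, ties.method = "first")
      md <- d2[cbind(seq_len(nrow(cc)), mi)]
      upd <- md < nearest_d2
      nearest_d2[upd] <- md[upd]
      nearest_i[upd] <- (s:e)[mi[upd]]
    }
    hit <- nearest_d2 <= cfg$tube_radius^2
    tract[cand[hit]] <- TRUE
    fib_idx <- cand[hit]
    fib_dir <- alltan[nearest_i[hit], , drop = FALSE]
    fib_frac <- rep(cfg$f_fiber, length(fib_idx))
  }

  # crossing tract: straight tube along x through the fan body
  crossing_mask <- array(FALSE, d)
  if (isTRUE(cfg$crossing)) {
    dy <- centers[, 2] - cfg$crossing_y
    dz <- centers[, 3] - cfg$crossing_z
    in_cross <- dy^2 + dz^2 <= cfg$tube_radius^2
    crossing_mask[in_cross] <- TRUE
    ci <- which(in_cross)
    # in overlap voxels the two populations share the fiber fraction
    overlap <- ci %in% fib_idx
    fib_frac[match(ci[overlap], fib_idx)] <- cfg$f_fiber / 2
    fib_idx <- c(fib_idx, ci)
    fib_dir <- rbind(fib_dir, matrix(rep(c(1, 0, 0), length(ci)),
                                     ncol = 3, byrow = TRUE))
    fib_frac <- c(fib_frac, ifelse(overlap, cfg$f_fiber / 2, cfg$f_fiber))
  }

  any_fiber <- array(FALSE, d)
  any_fiber[fib_idx] <- TRUE
  tissue <- dilate_mask(any_fiber, cfg$tissue_margin / cfg$voxel_size)

  iso_fraction <- array(0, d)
  iso_diffusivity <- array(0, d)
  iso_fraction[tissue] <- 1
  iso_diffusivity[tissue] <- cfg$d_background
  # fiber voxels: remaining fraction is CSF-like isotropic
  fsum <- tapply(fib_frac, fib_idx, sum)
  vidx <- as.integer(names(fsum))
  iso_fraction[vidx] <- pmax(0, 1 - as.numeric(fsum))
  iso_diffusivity[vidx] <- cfg$d_iso

  prob <- gauss_blur3d(array(as.numeric(tract), d), cfg$prob_sigma)
  prob <- prob / max(prob)
  prob[tract] <- pmax(prob[tract], 1e-6)  # truth always inside the support

  starts <- do.call(rbind, lapply(curves, `[[`, "start"))
  ends <- do.call(rbind, lapply(curves, `[[`, "end"))
  seed_mask <- array(FALSE, d)
  dist2_to <- function(pts) {
    m <- rep(Inf, nvox)
    for (r in seq_len(nrow(pts)))
      m <- pmin(m, rowSums(sweep(centers, 2, pts[r, ], `-`)^2))
    m
  }
  seed_mask[dist2_to(starts) <= cfg$seed_radius^2] <- TRUE
  target_mask <- array(FALSE, d)
  target_mask[dist2_to(ends) <= cfg$target_radius^2] <- TRUE

  structure(list(
    shape = as.integer(d), affine = affine, voxel_size = cfg$voxel_size,
    fibers = list(idx = fib_idx, dir = fib_dir, frac = fib_frac),
    iso_fraction = iso_fraction, iso_diffusivity = iso_diffusivity,
    tract_mask = tract, crossing_mask = crossing_mask,
    tissue_mask = tissue, seed_mask = seed_mask, target_mask = target_mask,
    tract_probability_map = prob,
    landmarks = list(tp = cfg$tp, op = cfg$op, apex = cfg$apex,
                     anterior_tip = cfg$apex),
    lambda_fiber = cfg$lambda_fiber,
    config = cfg, seed = as.integer(seed)),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d x %d voxels @ %.2f mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size))
  cat(sprintf("  tract %d voxels, tissue %d voxels, seed %d, target %d\n",
              sum(x$tract_mask), sum(x$tissue_mask), sum(x$seed_mask),
              sum(x$target_mask)))
  cat(sprintf("  anterior tip (apex) at y = %.1f mm; TP y = %.1f, OP y = %.1f\n",
              x$landmarks$apex[2], x$landmarks$tp[2], x$landmarks$op[2]))
  invisible(x)
}

#' Multi-tensor diffusion signal of a single voxel
#'
#' Closed-form noiseless forward model
#' \deqn{S(g, b) = s_0 [ f_{iso} e^{-b d_{iso}} + \sum_k f_k e^{-b g^T D_k g} ]}
#' with axially oriented compartment tensors built from `lambda` eigenvalues
#' (principal axis = the compartment orientation).
#'
#' @param scheme a `gradient_scheme`.
#' @param s0 unweighted signal.
#' @param orientations k x 3 matrix of unit fiber orientations (may be NULL).
#' @param fractions length-k fiber volume fractions.
#' @param lambda tensor eigenvalues (mm^2/s), descending.
#' @param f_iso,d_iso isotropic fraction and diffusivity.
#' @return numeric vector of per-volume signals (b0 volumes included).
#' @export
dwi_signal <- function(scheme, s0 = 100, orientations = NULL,
                       fractions = numeric(0), lambda = c(1.7e-3, 0.3e-3, 0.3e-3),
                       f_iso = 1 - sum(fractions), d_iso = 3.0e-3) {
  nvol <- length(scheme$b_values)
  bv <- scheme$b_values
  sig <- rep(0, nvol)
  sig <- f_iso * exp(-bv * d_iso)
  if (!is.null(orientations) && length(fractions)) {
    orientations <- matrix(orientations, ncol = 3)
    dw <- scheme_dw_index(scheme)
    g <- scheme$directions
    for (k in seq_along(fractions)) {
      v <- orientations[k, ] / sqrt(sum(orientations[k, ]^2))
      # g' D g for an axially symmetric tensor
      gtdg <- lambda[3] + (lambda[1] - lambda[3]) * (g %*% v)^2
      if (abs(lambda[2] - lambda[3]) > 0) {
        # full tensor with a deterministic secondary frame
        e2 <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e2 <- e2 - sum(e2 * v) * v; e2 <- e2 / sqrt(sum(e2^2))
        e3 <- c(v[2] * e2[3] - v[3] * e2[2], v[3] * e2[1] - v[1] * e2[3],
                v[1] * e2[2] - v[2] * e2[1])
        D <- lambda[1] * outer(v, v) + lambda[2] * outer(e2, e2) +
          lambda[3] * outer(e3, e3)
        gtdg <- rowSums((g %*% D) * g)
      }
      contrib <- rep(0, nvol)
      contrib[dw] <- fractions[k] * exp(-bv[dw] * gtdg)
      contrib[-dw] <- fractions[k]
      sig <- sig + contrib
    }
  }
  s0 * sig
}

#' Simulate a diffusion-weighted volume from a phantom
#'
#' Evaluates the multi-tensor forward model in every voxel and corrupts the
#' complex signal with Gaussian noise of standard deviation `s0 / snr`
#' before taking the magnitude (Rician noise).  SNR is referenced to the b0
#' signal; `snr = Inf` returns the noiseless signal.
#'
#' @param phantom a [build_or_phantom()] result.
#' @param scheme a `gradient_scheme`.
#' @param s0 unweighted tissue signal (arbitrary units).
#' @param snr signal-to-noise ratio of the b0 volume (or `Inf`).
#' @param seed integer noise seed.
#' @return object of class `dwi_volume`: 4-D array `data`
#'   (x, y, z, volume), `affine`, and the `scheme`.
#' @export
simulate_dwi <- function(phantom, scheme, s0 = 100, snr = 30, seed = 1L) {
  if (!(snr > 0)) stop("invalid argument: snr must be > 0 (may be Inf)")
  d <- phantom$shape
  nvol <- length(scheme$b_values)
  bv <- scheme$b_values
  dat <- array(0, c(d, nvol))
  nvox <- prod(d)

  # isotropic compartments, grouped by distinct (fraction, diffusivity)
  iso_f <- as.vector(phantom$iso_fraction)
  iso_d <- as.vector(phantom$iso_diffusivity)
  grp <- interaction(iso_f, iso_d, drop = TRUE)
  flat <- matrix(0, nvox, nvol)
  for (g in levels(grp)) {
    sel <- grp == g
    fi <- iso_f[which(sel)[1]]; di <- iso_d[which(sel)[1]]
    if (fi <= 0) next
    flat[sel, ] <- rep(s0 * fi * exp(-bv * di), each = sum(sel))
  }
  # fiber compartments (axially symmetric tensors)
  fib <- phantom$fibers
  if (length(fib$idx)) {
    lam <- phantom$lambda_fiber
    dw <- scheme_dw_index(scheme)
    dots2 <- (fib$dir %*% t(scheme$directions))^2
    gtdg <- lam[3] + (lam[1] - lam[3]) * dots2    # nfib x ndir
    att <- exp(-sweep(gtdg, 2, bv[dw], `*`))
    contrib_dw <- fib$frac * att * s0
    b0i <- scheme_b0_index(scheme)
    for (r in seq_along(fib$idx)) {
      flat[fib$idx[r], dw] <- flat[fib$idx[r], dw] + contrib_dw[r, ]
      flat[fib$idx[r], b0i] <- flat[fib$idx[r], b0i] + fib$frac[r] * s0
    }
  }

  if (is.finite(snr)) {
    sigma <- s0 / snr
    flat <- with_seed(seed, {
      n1 <- matrix(rnorm(length(flat), sd = sigma), nrow(flat))
      n2 <- matrix(rnorm(length(flat), sd = sigma), nrow(flat))
      sqrt((flat + n1)^2 + n2^2)
    })
  }
  dat <- array(flat, c(d, nvol))
  structure(list(data = dat, affine = phantom$affine, scheme = scheme),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d volumes (b max %g)\n",
              d[1], d[2], d[3], d[4], max(x$scheme$b_values)))
  invisible(x)
}
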