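# a uniform delta-FOD field pointing along +y on a straight-tube grid
delta_fod_field <- function(d = c(7L, 31L, 7L), v = c(0, 1, 0),
                            affine = diag(4)) {
  coef1 <- as.vector(sh_basis(matrix(v, 1), 6))
  coef <- array(rep(coef1, each = prod(d)), c(d, 28))
  structure(list(coef = coef, lmax = 6, mask = array(TRUE, d),
                 affine = affine), class = "fod_field")
}

test_that("the curvature cone follows the arc-chord relation", {
  expect_equal(cone_angle_deg(0.2, 0.3), 2 * asin(0.2 / 0.6) * 180 / pi)
  expect_equal(cone_angle_deg(0.2, 0.3), 38.9424, tolerance = 1e-4)
  expect_equal(tracking_params()$cone_angle, cone_angle_deg(0.2, 0.3))
  expect_error(tracking_params(step_length = 0), "invalid")
  expect_error(tracking_params(min_radius_of_curvature = -1), "invalid")
})

test_that("streamlines in a uniform +y delta field run straight along +y", {
  fod <- delta_fod_field()
  d <- dim(fod$mask)
  seeds <- array(FALSE, d); seeds[4, 16, 4] <- TRUE
  incl <- array(TRUE, d)
  p <- tracking_params(streamlines_per_seed_voxel = 50L, step_length = 0.2,
                       max_length = 80, seed = 5)
  set <- propagate(fod, seeds, incl, p)
  expect_equal(set$initiated, 50)
  for (m in set$points) {
    expect_gt(nrow(m), 10)
    ete <- m[nrow(m), ] - m[1, ]
    expect_lt(angle_between_deg(ete, c(0, 1, 0)), 5)
    # consecutive points exactly one step apart
    steps <- sqrt(rowSums(diff(m)^2))
    expect_lt(max(abs(steps - p$step_length)), 1e-6)
    # curvature cone never violated
    if (nrow(m) > 2) {
      seg <- diff(m)
      cosang <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE]) /
        (p$step_length^2)
      expect_gte(min(cosang), cos(p$cone_angle * pi / 180) - 1e-9)
    }
  }
})

test_that("seeding conserves counts and skips sub-threshold seed voxels", {
  fod <- delta_fod_field()
  d <- dim(fod$mask)
  seeds <- array(FALSE, d); seeds[3:4, 16, 4] <- TRUE
  incl <- array(TRUE, d)
  incl[3, 16, 4] <- FALSE   # below the FA threshold
  p <- tracking_params(streamlines_per_seed_voxel = 20L, seed = 1)
  expect_warning(set <- propagate(fod, seeds, incl, p), "below the FA threshold")
  expect_equal(set$initiated, 20)              # one eligible voxel x 20
  expect_equal(set$n_seed_voxels, 1)
  expect_equal(set$n_seed_voxels_skipped, 1)
  expect_error(propagate(fod, array(FALSE, d), incl, p), "empty seed")
})

test_that("tracking is deterministic for a fixed seed", {
  fod <- delta_fod_field()
  d <- dim(fod$mask)
  seeds <- array(FALSE, d); seeds[4, 16, 4] <- TRUE
  p <- tracking_params(streamlines_per_seed_voxel = 10L, seed = 77)
  s1 <- propagate(fod, seeds, array(TRUE, d), p)
  s2 <- propagate(fod, seeds, array(TRUE, d), p)
  expect_identical(s1$points, s2$points)
})

test_that("mask logic retains, rejects and truncates as specified", {
  d <- c(10L, 10L, 3L)
  aff <- diag(4)
  # masks addressed at 0-based voxels (identity affine: voxel = round(world))
  waypoint <- array(FALSE, d); waypoint[5 + 1, 5 + 1, 1 + 1] <- TRUE
  target <- array(FALSE, d); target[9 + 1, 5 + 1, 1 + 1] <- TRUE
  exclusion <- array(FALSE, d); exclusion[7 + 1, 5 + 1, 1 + 1] <- TRUE
  termination <- array(FALSE, d)

  mkset <- function(pts) structure(
    list(points = list(pts), status = "candidate", initiated = 1L,
         n_seed_voxels = 1L, affine = aff, dim = d,
         params = tracking_params(seed = 1)), class = "streamline_set")
  # passes waypoint then target, avoids exclusion (steps around x = 6 in y)
  good <- cbind(c(2, 5, 6, 6, 8, 9), c(5, 5, 5, 7, 7, 5), 1)
  f <- filter_streamlines(mkset(good), waypoint, target, exclusion, termination)
  expect_equal(f$retained, 1)
  expect_equal(f$status, "retained")
  # same path through the exclusion voxel
  bad <- cbind(2:9, 5, 1)
  f2 <- filter_streamlines(mkset(bad), waypoint, target, exclusion, termination)
  expect_equal(f2$retained, 0)
  expect_equal(f2$status, "rejected:exclusion")
  # waypoint but never target
  short <- cbind(2:6, 5, 1)
  f3 <- filter_streamlines(mkset(short), waypoint, target, exclusion, termination)
  expect_equal(f3$status, "rejected:no-target")
  # no waypoint
  off <- cbind(2:9, 2, 1)
  f4 <- filter_streamlines(mkset(off), waypoint, target, exclusion, termination)
  expect_equal(f4$status, "rejected:no-waypoint")
  # truncation at the termination plane cuts the tail before the target
  term2 <- array(FALSE, d); term2[8 + 1, , ] <- TRUE
  f5 <- filter_streamlines(mkset(bad), waypoint, target, NULL, term2)
  expect_equal(f5$status, "rejected:no-target")
  expect_equal(nrow(filter_streamlines(mkset(bad), NULL, NULL, NULL,
                                       term2)$points[[1]]), 7)
})

test_that("SDI uses binary per-streamline visitation normalized by retained count", {
  d <- c(6L, 6L, 1L)
  aff <- diag(4)
  s1 <- cbind(0:4, 2, 0)
  sdi1 <- compute_sdi(list(s1), d, aff)
  expect_equal(sum(sdi1$data == 1), 5)
  expect_equal(sum(sdi1$data), 5)
  # two disjoint paths -> 0.5 each
  s2 <- cbind(0:4, 4, 0)
  sdi2 <- compute_sdi(list(s1, s2), d, aff)
  expect_true(all(sdi2$data[sdi2$data > 0] == 0.5))
  # re-entering a voxel twice still counts once
  s3 <- cbind(c(0, 1, 0, 1), 1, 0)
  sdi3 <- compute_sdi(list(s3), d, aff)
  expect_equal(max(sdi3$data), 1)
  expect_equal(sum(sdi3$data > 0), 2)
  expect_true(all(sdi3$data >= 0 & sdi3$data <= 1))
  expect_error(compute_sdi(list(), d, aff), "zero retained")
})

test_that("streamlines round-trip through TCK files", {
  pts <- list(cbind(c(0, 0.2, 0.4), c(1, 1, 1.1), c(2, 2, 2)),
              cbind(c(5, 5.5), c(-1, -1.2), c(0, 0.1)))
  td <- withr::local_tempdir()
  path <- file.path(td, "tracks.tck")
  write_tck(pts, path)
  back <- read_tck(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]], pts[[1]], tolerance = 1e-6)
  expect_equal(back[[2]], pts[[2]], tolerance = 1e-6)
})
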