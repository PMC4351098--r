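test_that("trilinear resampling reproduces identity, shifts and impulses", {
  a <- array(runif(5 * 6 * 4), c(5, 6, 4))
  aff <- diag(4)
  # identity: exact copy
  expect_equal(resample_affine(a, aff, dim(a), aff), a, tolerance = 1e-12)
  # translation by exactly one voxel along x
  aff_shift <- diag(4); aff_shift[1, 4] <- 1
  out <- resample_affine(a, aff, dim(a), aff_shift)
  expect_equal(out[1:4, , ], a[2:5, , ], tolerance = 1e-12)
  expect_true(all(out[5, , ] == 0))   # out-of-field zeros
  # half-voxel translation of an impulse: two voxels at 0.5
  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 1
  aff_half <- diag(4); aff_half[1, 4] <- 0.5
  oh <- resample_affine(imp, diag(4), dim(imp), aff_half)
  expect_equal(oh[2, 3, 3], 0.5)
  expect_equal(oh[3, 3, 3], 0.5)
  expect_equal(sum(oh), 1)
  expect_error(resample_affine(imp, matrix(0, 4, 4), dim(imp), diag(4)),
               "invalid")
})

test_that("probability thresholding is strict, monotone, and errors when empty", {
  p <- array(c(0, 0.05, 0.15, 0.5, rep(0, 4)), c(8, 1, 1))
  expect_equal(sum(probability_to_mask(p, 0.1)), 2)
  expect_equal(sum(probability_to_mask(p, 0)), 3)   # strictly positive only
  expect_error(probability_to_mask(p, 1), "threshold 1")
  expect_error(probability_to_mask(array(2, c(2, 1, 1)), 0.5), "invalid")
  # monotonicity: raising the threshold never adds voxels
  pr <- array(withr::with_seed(1, runif(1000)), c(10, 10, 10))
  thr <- seq(0, 0.9, by = 0.1)
  counts <- vapply(thr, function(t) sum(probability_to_mask(pr, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("plane masks land on the coronal/sagittal slices given by the affine", {
  d <- c(20L, 50L, 10L)
  aff <- diag(c(2.5, 2.5, 2.5, 1))
  or_mask <- array(FALSE, d)
  or_mask[8:12, 10:40, 4:6] <- TRUE
  pl <- make_planes(or_mask, aff, tp = c(25, 100, 10), midline_x = 0)
  # waypoint: coronal slice nearest y = 100 - 60 = 40 mm -> index 16
  expect_equal(pl$waypoint_slice, 16L)
  # exclusion: coronal slice nearest y = 80 mm -> index 32
  expect_equal(pl$exclusion_slice, 32L)
  # waypoint is a subset of the tract mask
  expect_true(all(or_mask[pl$waypoint]))
  expect_equal(sum(pl$waypoint), sum(or_mask[, 17, ]))
  # disjoint planes when offsets differ by more than a voxel
  expect_equal(sum(pl$waypoint & pl$exclusion), 0)
  # termination: full sagittal plane at x = 0 -> index 0
  expect_equal(pl$termination_slice, 0L)
  expect_equal(sum(pl$termination), prod(d[2:3]))
  # empty waypoint slice errors
  or2 <- array(FALSE, d); or2[8:12, 30:40, 4:6] <- TRUE
  expect_error(make_planes(or2, aff, tp = c(25, 100, 10)), "empty waypoint")
  expect_error(make_planes(or_mask, aff, tp = c(25, 400, 10)), "invalid")
})

test_that("FA inclusion mask thresholds strictly and splits hemispheres", {
  d <- c(10L, 8L, 6L)
  aff <- diag(4); aff[1, 4] <- -4.5   # midline through the grid center
  fa <- array(0.05, d)
  expect_error(make_inclusion_mask(fa, aff), "empty")
  fa[3:8, 2:6, 2:4] <- 0.5
  m <- make_inclusion_mask(fa, aff)
  expect_equal(sum(m), sum(fa > 0.1))
  # mirrored map: equal voxel counts in the two hemispheres
  fa_sym <- fa
  fa_sym[] <- pmax(fa, fa[d[1]:1, , ])
  ml <- make_inclusion_mask(fa_sym, aff, hemisphere = "left", midline_x = 0)
  mr <- make_inclusion_mask(fa_sym, aff, hemisphere = "right", midline_x = 0)
  expect_equal(sum(ml), sum(mr))
  expect_equal(sum(ml & mr), 0)
})
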