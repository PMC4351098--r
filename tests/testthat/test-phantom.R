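test_that("phantom geometry satisfies its construction invariants", {
  ph <- build_or_phantom(phantom_config(), seed = 1)
  expect_gt(sum(ph$tract_mask), 0)
  # recorded anterior tip equals the configured apex
  expect_equal(ph$landmarks$anterior_tip, phantom_config()$apex)
  # volume fractions per voxel in [0, 1] and summing to <= 1
  expect_true(all(ph$fibers$frac >= 0 & ph$fibers$frac <= 1))
  sums <- tapply(ph$fibers$frac, ph$fibers$idx, sum)
  expect_true(all(sums <= 1 + 1e-12))
  # fiber orientations are unit vectors
  expect_true(all(abs(sqrt(rowSums(ph$fibers$dir^2)) - 1) < 1e-8))
  # tract mask inside the probability-map support
  expect_true(all(ph$tract_probability_map[ph$tract_mask] > 0))
  expect_true(max(ph$tract_probability_map) == 1)
  # landmarks inside the grid
  ext <- (ph$shape - 1) * ph$voxel_size
  for (lm in ph$landmarks[c("tp", "op", "apex")])
    expect_true(all(lm >= 0 & lm <= ext))
  # the apex really is the anteriormost centerline point: no tract voxel
  # lies more than a tube radius anterior to it
  idx <- which(ph$tract_mask, arr.ind = TRUE) - 1
  expect_lte(max(idx[, 2] * ph$voxel_size),
             ph$landmarks$apex[2] + ph$config$tube_radius)
})

test_that("crossing region carries two fiber populations, fan collapses at zero spread", {
  ph <- build_or_phantom(phantom_config(), seed = 1)
  two_pop <- ph$fibers$idx[duplicated(ph$fibers$idx)]
  expect_gt(length(two_pop), 0)
  sums <- tapply(ph$fibers$frac, ph$fibers$idx, sum)
  expect_true(all(sums[as.character(two_pop)] <= 1))

  tube <- build_or_phantom(
    phantom_config(fan_spread = 0, fan_spread_x = 0, n_fan = 1L,
                   crossing = FALSE), seed = 1)
  # single curved tube: every tract voxel within a tube radius of one curve
  expect_lt(sum(tube$tract_mask), sum(ph$tract_mask))
  expect_equal(sum(duplicated(tube$fibers$idx)), 0)
})

test_that("apex outside the grid is rejected", {
  expect_error(build_or_phantom(phantom_config(apex = c(60, 500, 25))),
               "invalid")
  expect_error(build_or_phantom(phantom_config(shape = c(10L, 10L, 5L))),
               "invalid")
})

test_that("noiseless forward model matches the closed-form tensor signal", {
  sch <- fixture_scheme()
  # isotropic voxel at b = 0 gives exactly s0
  sig_iso <- dwi_signal(sch, s0 = 100, f_iso = 1, d_iso = 1e-3)
  expect_equal(sig_iso[1], 100)
  # single tensor: -log(S/s0)/b equals g' D g for every direction
  v <- c(1, 2, -1) / sqrt(6)
  lam <- c(1.7e-3, 0.3e-3, 0.3e-3)
  sig <- dwi_signal(sch, 100, v, 1, lambda = lam, f_iso = 0)
  dwv <- sig[sch$n_b0 + seq_len(30)]
  adc_meas <- -log(dwv / 100) / 3000
  gtdg <- lam[3] + (lam[1] - lam[3]) * (sch$directions %*% v)^2
  expect_equal(adc_meas, as.vector(gtdg), tolerance = 1e-10)
})

test_that("simulated DWI is nonnegative, deterministic, and Rician-calibrated", {
  ph <- build_or_phantom(small_phantom_config(), seed = 1)
  nb0 <- 9L
  sch <- generate_gradient_scheme(6, 3000, nb0, seed = 2)
  d1 <- simulate_dwi(ph, sch, snr = 30, seed = 4)
  d2 <- simulate_dwi(ph, sch, snr = 30, seed = 4)
  expect_identical(d1$data, d2$data)
  expect_true(all(d1$data >= 0))
  expect_error(simulate_dwi(ph, sch, snr = -2), "invalid")

  # noise calibration: mean of >= 1e4 noisy b0 samples matches the Rician
  # mean (numerical-integration oracle) within 2%
  b0 <- as.vector(d1$data[, , , seq_len(nb0)])[rep(ph$tissue_mask, nb0)]
  expect_gte(length(b0), 1e4)
  oracle <- rician_mean(100, 100 / 30)
  expect_equal(mean(b0) / oracle, 1, tolerance = 0.02)

  # noiseless b0 equals s0 exactly in pure-isotropic voxels
  dn <- simulate_dwi(ph, sch, snr = Inf, seed = 1)
  iso_only <- ph$tissue_mask & !(seq_along(ph$tissue_mask) %in% ph$fibers$idx)
  expect_equal(unique(round(dn$data[, , , 1][iso_only], 10)), 100)
})

test_that("DTI on noiseless phantom output recovers the input tensor", {
  sch <- fixture_scheme()
  v <- c(0.3, -0.5, 0.81)
  sig <- dwi_signal(sch, 100, v, 1, f_iso = 0)
  tf <- fit_dti(as_dwi(sig, sch))
  lam_true <- c(1.7e-3, 0.3e-3, 0.3e-3)
  expect_equal(tf$evals[1, 1, 1, ], lam_true, tolerance = 1e-8)
  expect_equal(tf$fa[1, 1, 1], fa_from_eigenvalues(lam_true), tolerance = 1e-8)
})

test_that("DWI volumes round-trip through NIfTI with gradient tables", {
  ph <- build_or_phantom(small_phantom_config(), seed = 1)
  sch <- generate_gradient_scheme(6, 2000, 1, seed = 3)
  dwi <- simulate_dwi(ph, sch, snr = 30, seed = 2)
  td <- withr::local_tempdir()
  write_dwi_nifti(dwi, file.path(td, "sub"))
  back <- read_dwi_nifti(file.path(td, "sub"))
  expect_equal(dim(back$data), dim(dwi$data))
  expect_equal(as.vector(back$data), as.vector(dwi$data), tolerance = 1e-6)
  expect_equal(unclass(back$affine), unclass(dwi$affine), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$scheme$directions, sch$directions, tolerance = 1e-8)
})
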