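test_that("response estimation reorients, fits zonally, and reconvolves", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  tf <- fit_dti(sf$dwi)
  resp <- estimate_response(sf$dwi, sch, tf, fa_cutoff = 0.7)
  expect_gt(resp$rl[1], 0)
  # the signal has its minimum along the fiber: negative zonal l = 2 term
  expect_lt(resp$rl[2], 0)
  # reconvolution oracle: response (*) delta(+z) evaluated at the gradient
  # directions reproduces the aligned single-fiber signal within 2% RMS of
  # the unweighted signal
  pred <- response_signal(resp, sch$directions)
  truth <- dwi_signal(sch, 1, c(0, 0, 1), 1, f_iso = 0)[-seq_len(sch$n_b0)]
  expect_lt(sqrt(mean((pred - truth)^2)), 0.02)
})

test_that("response estimation fails cleanly without anisotropic voxels", {
  sch <- fixture_scheme()
  sig <- t(replicate(20, dwi_signal(sch, 100, f_iso = 1, d_iso = 1e-3)))
  dwi <- as_dwi(sig, sch)
  tf <- fit_dti(dwi)
  expect_error(estimate_response(dwi, sch, tf, fa_cutoff = 0.7),
               "insufficient data.*0 voxels")
})

test_that("CSD of response (*) delta recovers the fiber direction", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
  sig <- c(1, response_signal(resp, sch$directions))
  fod <- csd_fit(as_dwi(sig, sch), sch, resp, lmax = 6)
  expect_equal(dim(fod$coef)[4], 28)
  pk <- fod_peaks(fod$coef[1, 1, 1, ])
  expect_lt(angle_between_deg(pk[1, ], c(0, 0, 1)), 2)
  # soft non-negativity: no amplitude strongly negative
  amps <- fod_amplitudes(fod$coef[1, 1, 1, ], sphere_grid(300))
  expect_gte(min(amps), -0.1 * mean(amps))
})

test_that("CSD resolves a 90-degree crossing at SNR 30", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
  sig <- dwi_signal(sch, 100, rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5),
                    f_iso = 0)
  noisy <- ricianize(sig, 100 / 30, seed = 42)
  fod <- csd_fit(as_dwi(noisy, sch), sch, resp, lmax = 6)
  pk <- fod_peaks(fod$coef[1, 1, 1, ], min_relative_amplitude = 0.3)
  expect_gte(nrow(pk), 2)
  a_x <- min(apply(pk, 1, angle_between_deg, b = c(1, 0, 0)))
  a_y <- min(apply(pk, 1, angle_between_deg, b = c(0, 1, 0)))
  expect_lt(a_x, 10)
  expect_lt(a_y, 10)
  amp <- attr(pk, "amplitudes")
  # near-equal true fibers: amplitude ratio within [1/1.4, 1]
  expect_gte(amp[2] / amp[1], 1 / 1.4)
  expect_lte(amp[2] / amp[1], 1)
})

test_that("deconvolution sharpens: FOD of the response beats the raw signal", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
  sig <- c(1, response_signal(resp, sch$directions))
  fod <- csd_fit(as_dwi(sig, sch), sch, resp, lmax = 6)
  g <- sphere_grid(2000)
  # mean-normalized peakedness: max amplitude over spherical mean
  sharp <- function(a) max(a) / mean(a)
  fod_amp <- fod_amplitudes(fod$coef[1, 1, 1, ], g)
  sig_amp <- response_signal(resp, g)
  expect_gt(sharp(fod_amp), sharp(sig_amp))
})

test_that("CSD peaks are rotation equivariant", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
  v <- c(0, 0, 1)
  th <- 0.9
  R <- matrix(c(1, 0, 0,
                0, cos(th), sin(th),
                0, -sin(th), cos(th)), 3, 3)
  sig1 <- dwi_signal(sch, 100, v, 1, f_iso = 0)
  fod1 <- csd_fit(as_dwi(sig1, sch), sch, resp, lmax = 6)
  pk1 <- fod_peaks(fod1$coef[1, 1, 1, ])[1, ]
  sch_rot <- sch
  sch_rot$directions <- sch$directions %*% t(R)
  sig2 <- dwi_signal(sch_rot, 100, as.vector(R %*% v), 1, f_iso = 0)
  fod2 <- csd_fit(as_dwi(sig2, sch_rot), sch_rot, resp, lmax = 6)
  pk2 <- fod_peaks(fod2$coef[1, 1, 1, ])[1, ]
  expect_lt(angle_between_deg(as.vector(R %*% pk1), pk2), 1)
})

test_that("higher b-value improves angular resolution of a 45-degree crossing", {
  v1 <- c(1, 0, 0)
  v2 <- c(cos(pi / 4), sin(pi / 4), 0)
  resolved_frac <- function(bval, seeds) {
    sch <- generate_gradient_scheme(30, bval, 1, seed = 1)
    sf <- single_fiber_volume(sch)
    resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
    sig <- dwi_signal(sch, 100, rbind(v1, v2), c(0.5, 0.5), f_iso = 0)
    mean(vapply(seeds, function(s) {
      noisy <- ricianize(sig, 100 / 30, seed = s)
      fod <- csd_fit(as_dwi(noisy, sch), sch, resp, lmax = 6)
      pk <- fod_peaks(fod$coef[1, 1, 1, ], min_relative_amplitude = 0.3)
      nrow(pk) >= 2 &&
        min(apply(pk, 1, angle_between_deg, b = v1)) < 20 &&
        min(apply(pk, 1, angle_between_deg, b = v2)) < 20
    }, logical(1)))
  }
  expect_gte(resolved_frac(3000, 1:20), resolved_frac(1000, 1:20))
})

test_that("fod_peaks handles constructed multi-peak and degenerate inputs", {
  # two orthogonal equal deltas
  coef <- as.vector(sh_basis(matrix(c(1, 0, 0), 1), 6) +
                    sh_basis(matrix(c(0, 1, 0), 1), 6))
  pk <- fod_peaks(coef, min_relative_amplitude = 0.5)
  expect_equal(nrow(pk), 2)
  # threshold above the maximum drops everything
  expect_equal(nrow(fod_peaks(coef, min_relative_amplitude = 1.01)), 0)
  # all-zero coefficients give an empty peak list
  expect_equal(nrow(fod_peaks(rep(0, 28))), 0)
  expect_error(fod_peaks(coef, grid = sphere_grid(50)), "invalid")
})

test_that("csd_fit validates inputs and handles an empty mask", {
  sch <- fixture_scheme()
  sf <- single_fiber_volume(sch)
  resp <- estimate_response(sf$dwi, sch, fit_dti(sf$dwi), fa_cutoff = 0.7)
  sig <- c(1, response_signal(resp, sch$directions))
  dwi <- as_dwi(sig, sch)
  expect_error(csd_fit(dwi, sch, resp, lmax = 5), "invalid")
  expect_warning(f0 <- csd_fit(dwi, sch, resp, mask = array(FALSE, c(1, 1, 1))),
                 "empty")
  expect_true(all(f0$coef == 0))
  resp2 <- resp; resp2$b_value <- 1000
  expect_error(csd_fit(dwi, sch, resp2), "b-value")
})
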