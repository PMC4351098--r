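test_that("single-stick truth is recovered at SNR 30", {
  sch <- fixture_scheme()
  sig <- dwi_signal(sch, 100, c(1, 0, 0), 0.6, lambda = c(1.7e-3, 0, 0),
                    f_iso = 0.4, d_iso = 1.7e-3)
  noisy <- ricianize(sig, 100 / 30, seed = 11)
  fit <- ballstick_fit(as_dwi(noisy, sch), sch, n_sticks = 1, seed = 3)
  sm <- ballstick_summary(fit, 1)
  expect_lt(abs(sm$mean_f[1] - 0.6), 0.05)
  expect_lt(angle_between_deg(sm$mean_dir[1, ], c(1, 0, 0)), 5)
})

test_that("isotropic voxels yield near-zero stick fractions", {
  sch <- fixture_scheme()
  sig <- dwi_signal(sch, 100, f_iso = 1, d_iso = 0.8e-3)
  noisy <- ricianize(sig, 100 / 30, seed = 12)
  fit <- ballstick_fit(as_dwi(noisy, sch), sch, n_sticks = 1, seed = 3)
  expect_lt(ballstick_summary(fit, 1)$mean_f[1], 0.1)
})

test_that("posterior draws respect the model constraints", {
  sch <- fixture_scheme()
  sig <- dwi_signal(sch, 100, rbind(c(1, 0, 0), c(0, 1, 0)), c(0.4, 0.3),
                    lambda = c(1.7e-3, 0, 0), f_iso = 0.3, d_iso = 1.7e-3)
  noisy <- ricianize(sig, 100 / 30, seed = 13)
  fit <- ballstick_fit(as_dwi(noisy, sch), sch, n_sticks = 2, seed = 4)
  expect_gte(fit$n_samples, 50)
  # per-draw fraction sums <= 1, fractions in [0, 1]
  fsum <- apply(fit$f, c(1, 3), sum)
  expect_true(all(fit$f >= 0 & fit$f <= 1))
  expect_true(all(fsum <= 1))
  # orientations unit norm
  nrm <- sqrt(apply(fit$dir^2, c(1, 2, 4), sum))
  expect_true(all(abs(nrm - 1) < 1e-8))
  expect_true(all(fit$d > 0 & fit$d < 1e-2))
})

test_that("identical seeds give identical chains; bad arguments error", {
  sch <- fixture_scheme()
  sig <- ricianize(dwi_signal(sch, 100, c(0, 0, 1), 0.5,
                              lambda = c(1.7e-3, 0, 0), f_iso = 0.5,
                              d_iso = 1.7e-3), 100 / 30, seed = 1)
  dwi <- as_dwi(sig, sch)
  f1 <- ballstick_fit(dwi, sch, n_sticks = 2, seed = 9)
  f2 <- ballstick_fit(dwi, sch, n_sticks = 2, seed = 9)
  expect_identical(f1$f, f2$f)
  expect_identical(f1$dir, f2$dir)
  expect_false(identical(f1$f, ballstick_fit(dwi, sch, n_sticks = 2,
                                             seed = 10)$f))
  expect_error(ballstick_fit(dwi, sch, n_sticks = 4), "invalid")
  expect_error(ballstick_fit(dwi, sch, mcmc = list(burn_in = -1,
                                                   n_samples = 50, thin = 2)),
               "invalid")
})

test_that("90% credible intervals cover the true fraction in most repeats", {
  sch <- fixture_scheme()
  sig <- dwi_signal(sch, 100, c(1, 0, 0), 0.6, lambda = c(1.7e-3, 0, 0),
                    f_iso = 0.4, d_iso = 1.7e-3)
  cover <- vapply(1:50, function(s) {
    noisy <- ricianize(sig, 100 / 30, seed = 100 + s)
    fit <- ballstick_fit(as_dwi(noisy, sch), sch, n_sticks = 1, seed = s)
    ci <- ballstick_summary(fit, 1)$ci90_f
    ci[1] <= 0.6 && 0.6 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.7)
})
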