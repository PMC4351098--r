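# shared fixtures, all generated in code

# canonical 30-direction scheme reused across tests (computed once)
fixture_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- generate_gradient_scheme(30, 3000, 1, seed = 1)
    sch
  }
})

# wrap a per-voxel signal matrix (nvox x nvol) into a dwi_volume on a
# trivial grid
as_dwi <- function(signals, scheme, dim3 = NULL, affine = diag(4)) {
  signals <- matrix(signals, ncol = length(scheme$b_values))
  if (is.null(dim3)) dim3 <- c(nrow(signals), 1, 1)
  structure(list(data = array(signals, c(dim3, ncol(signals))),
                 affine = affine, scheme = scheme),
            class = "dwi_volume")
}

# add Rician noise to a signal vector
ricianize <- function(sig, sigma, seed) {
  withr::with_seed(seed, sqrt((sig + rnorm(length(sig), sd = sigma))^2 +
                                rnorm(length(sig), sd = sigma)^2))
}

# reduced-scale phantom for pipeline plumbing tests (geometry scaled to a
# 24 x 36 x 12 grid; same topology as the default)
small_phantom_config <- function(...) {
  phantom_config(shape = c(24L, 36L, 12L),
                 apex = c(35, 60, 15), loop_radius = 6,
                 seed_y = 42.5, target_y = 7.5,
                 fan_spread = 5, fan_spread_x = 4, n_fan = 5L,
                 crossing_y = 30, crossing_z = 15,
                 tp = c(30, 85, 15), op = c(35, 2.5, 15),
                 midline_x = 5, tissue_margin = 5,
                 seed_radius = 3.5, target_radius = 6, ...)
}

small_run_config <- function(...) {
  run_config(phantom = small_phantom_config(),
             mcmc = list(burn_in = 300L, n_samples = 30L, thin = 10L),
             tracking = tracking_params(streamlines_per_seed_voxel = 30L),
             n_subjects = 2L, ...)
}

# a single-fiber multi-voxel volume with varied orientations (for response
# estimation)
single_fiber_volume <- function(scheme, n = 30, seed = 5, snr = Inf,
                                f_iso = 0) {
  dirs <- withr::with_seed(seed, {
    m <- matrix(rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
  sig <- t(vapply(seq_len(n), function(i)
    dwi_signal(scheme, 100, dirs[i, ], 1 - f_iso, f_iso = f_iso),
    numeric(length(scheme$b_values))))
  if (is.finite(snr))
    sig <- matrix(ricianize(as.vector(sig), 100 / snr, seed + 1), nrow = n)
  list(dwi = as_dwi(sig, scheme), dirs = dirs)
}

# brute-force Mann-Whitney concordance probability (ROC oracle)
concordance_prob <- function(pos_values, neg_values) {
  s <- 0
  for (p in pos_values) for (n in neg_values)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos_values) * length(neg_values))
}

# exhaustive signed-rank two-sided p-value for small n (statistics oracle)
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Rician mean by numerical integration (noise-calibration oracle)
rician_mean <- function(nu, sigma) {
  integrate(function(x) x^2 / sigma^2 *
              exp(-(x - nu)^2 / (2 * sigma^2)) *
              besselI(x * nu / sigma^2, 0, expon.scaled = TRUE),
            lower = 0, upper = nu + 12 * sigma, rel.tol = 1e-9)$value
}

angle_between_deg <- function(a, b, axial = TRUE) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (axial) d <- abs(d)
  acos(min(max(d, -1), 1)) * 180 / pi
}
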