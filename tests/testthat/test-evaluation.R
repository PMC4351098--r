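test_that("a perfect classifier gives AUC = 1 and J = 1", {
  d <- c(6L, 6L, 2L)
  gold <- array(FALSE, d); gold[2:3, 2:4, 1] <- TRUE
  search <- array(TRUE, d)
  sdi <- array(0, d); sdi[gold] <- 1
  roc <- roc_analysis(sdi, gold, search)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_j, 1)
  expect_true(all(diff(roc$grid$fpr) > 0))
  expect_true(all(diff(roc$grid$tpr) >= 0))
})

test_that("uniform-noise densities give chance-level AUC", {
  d <- c(100L, 100L, 1L)
  search <- array(TRUE, d)
  gold <- array(FALSE, d); gold[, 1:30, 1] <- TRUE
  sdi <- array(withr::with_seed(7, runif(prod(d))), d)
  roc <- roc_analysis(sdi, gold, search)
  expect_equal(roc$auc, 0.5, tolerance = 0.05)
})

test_that("AUC equals the brute-force concordance probability (<= 15 voxels)", {
  for (s in 1:25) {
    inst <- withr::with_seed(s, {
      n <- sample(4:15, 1)
      npos <- sample(seq_len(n - 1), 1)
      v <- sample(c(runif(n), rep(0.3, 3)))[seq_len(n)]  # allow ties
      list(v = v, pos = seq_len(npos))
    })
    d <- c(length(inst$v), 1L, 1L)
    sdi <- array(inst$v, d)
    gold <- array(FALSE, d); gold[inst$pos, 1, 1] <- TRUE
    roc <- roc_analysis(sdi, gold, array(TRUE, d))
    oracle <- concordance_prob(inst$v[inst$pos], inst$v[-inst$pos])
    expect_equal(roc$auc, oracle, tolerance = 0.01)
  }
  expect_error(roc_analysis(array(1, c(2, 1, 1)), array(TRUE, c(2, 1, 1)),
                            array(TRUE, c(2, 1, 1))), "undefined")
})

test_that("threshold_at_fpr matches exhaustive enumeration and is monotone", {
  vals <- withr::with_seed(3, round(runif(20), 2))
  d <- c(20L, 1L, 1L)
  sdi <- array(vals, d)
  gold <- array(FALSE, d); gold[c(2, 5, 9, 14, 17), 1, 1] <- TRUE
  search <- array(TRUE, d)
  neg <- vals[-c(2, 5, 9, 14, 17)]
  enumerated <- function(target) {
    thr <- sort(unique(vals))
    fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
    thr[which(fpr <= target)[1]]
  }
  for (target in c(0, 0.05, 0.1, 0.3, 0.7, 1))
    expect_equal(threshold_at_fpr(sdi, gold, search, target),
                 enumerated(target))
  # boundaries: target 0 -> the maximum over non-gold voxels
  expect_equal(threshold_at_fpr(sdi, gold, search, 0), max(neg))
  # target 1 with a zero-valued voxel present -> threshold 0
  vals0 <- vals; vals0[1] <- 0
  expect_equal(threshold_at_fpr(array(vals0, d), gold, search, 1), 0)
  # monotone: raising the target never raises the threshold
  thrs <- vapply(seq(0, 1, by = 0.05),
                 function(t) threshold_at_fpr(sdi, gold, search, t), numeric(1))
  expect_true(all(diff(thrs) <= 0))
  expect_error(threshold_at_fpr(sdi, gold, search, 2), "invalid")
})

test_that("finalization applies the cross-subject median threshold", {
  d <- c(10L, 10L, 10L)
  aff <- diag(c(2.5, 2.5, 2.5, 1))
  mk <- function(v) structure(list(data = array(v, d), affine = aff,
                                   n_streamlines = 10), class = "sdi")
  s1 <- mk(rep(c(0.3, 0), c(500, 500)))
  fin <- finalize_tracts(list(s1, s1, s1), c(0.1, 0.2, 0.4))
  expect_equal(fin$threshold, 0.2)
  # 500 suprathreshold voxels at 2.5 mm isotropic: 500 x 15.625 / 1000 cm3
  expect_equal(fin$volumes_cm3, rep(500 * 2.5^3 / 1000, 3))
  # 1000 voxels -> 15.625 cm3
  s2 <- mk(rep(1, 1000))
  expect_equal(finalize_tracts(list(s2), 0.5)$volumes_cm3, 15.625)
  # single subject: median is that subject's threshold
  expect_equal(finalize_tracts(list(s1), 0.25)$threshold, 0.25)
  expect_warning(finalize_tracts(list(s1), 0.9), "empty final tract")
})

test_that("landmark distances use the anteriormost slice centroid on |dy|", {
  d <- c(20L, 30L, 10L)
  aff <- diag(c(2.5, 2.5, 2.5, 1))
  tract <- array(FALSE, d)
  tract[8:12, 5:20, 4:6] <- TRUE
  tp <- c(25, 70, 12); op <- c(25, 0, 12)
  lm <- measure_landmarks(tract, aff, tp, op)
  expect_equal(lm$mla[2], 19 * 2.5)          # most anterior occupied slice
  expect_equal(lm$mla[1], mean((7:11) * 2.5))  # slice centroid
  expect_equal(lm$mla_tp, 70 - 47.5)
  expect_equal(lm$mla_op, 47.5)
  expect_equal(lm$tp_op, 70)
  # translating the tract posteriorly increases MLA-TP by the same amount
  tract2 <- array(FALSE, d)
  tract2[8:12, 5:18, 4:6] <- TRUE            # 2 slices = 5 mm posterior
  lm2 <- measure_landmarks(tract2, aff, tp, op)
  expect_equal(lm2$mla_tp, lm$mla_tp + 5)
  expect_error(measure_landmarks(array(FALSE, d), aff, tp, op), "empty")
})

test_that("phantom gold-mask tip matches the recorded apex within one voxel", {
  ph <- build_or_phantom(phantom_config(), seed = 1)
  gold <- probability_to_mask(ph$tract_probability_map, 0.1)
  lm <- measure_landmarks(gold, ph$affine, ph$landmarks$tp, ph$landmarks$op)
  expect_lte(abs(lm$mla[2] - ph$landmarks$apex[2]), 2 * ph$voxel_size)
  lm_tract <- measure_landmarks(ph$tract_mask, ph$affine, ph$landmarks$tp,
                                ph$landmarks$op)
  expect_lte(abs(lm_tract$mla[2] - ph$landmarks$apex[2]), ph$voxel_size)
})

test_that("signed-rank p-values match exhaustive enumeration at n = 6", {
  diffs <- c(1.3, -0.4, 2.2, 0.7, -1.8, 0.9)
  a <- rnorm(6); b <- a - diffs
  res <- paired_tests(a, b)
  expect_equal(res$wilcoxon$p_value, signed_rank_exact_p(diffs))
  expect_equal(res$wilcoxon$method, "exact")
  # a second sign pattern
  diffs2 <- c(0.2, 0.5, 1.1, 2.3, 3.1, 4.0)
  res2 <- paired_tests(diffs2 + 5, rep(5, 6))
  expect_equal(res2$wilcoxon$p_value, signed_rank_exact_p(diffs2))
  expect_equal(res2$wilcoxon$p_value, 2 / 64)   # all positive: 2 * P(W >= 21)
})

test_that("degenerate paired inputs are flagged", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- paired_tests(x, x)
  expect_true(res$degenerate)
  expect_equal(res$wilcoxon$p_value, 1)
  # zero-mean differences give t = 0, p = 1
  b <- x - c(-1, 1, -2, 2, -3, 3)
  res2 <- paired_tests(x, b)
  expect_equal(res2$t$statistic, 0)
  expect_equal(res2$t$p_value, 1)
  expect_error(paired_tests(1:4, 2:5), "5")
  expect_error(paired_tests(1:6, 1:5), "unequal")
})

test_that("Dice coefficient covers identical, disjoint and partial overlap", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  b <- array(c(FALSE, FALSE, TRUE, TRUE), c(4, 1, 1))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0)
  cpy <- a; cpy[3, 1, 1] <- TRUE
  expect_equal(dice_coefficient(a, cpy), 2 * 2 / (2 + 3))
})
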