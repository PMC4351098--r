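#' Voxel-wise ROC analysis of a streamline-density image
#'
#' Sweeps every distinct SDI value as a threshold; at threshold t,
#' TPR = |{SDI > t} ∩ gold| / |gold| and
#' FPR = |{SDI > t} ∩ (search \\ gold)| / |search \\ gold|.  TPR is linearly
#' interpolated onto `n_points` equally spaced FPR values in [0, 1]
#' (anchored at (0,0) and (1,1)); the AUC is the trapezoid over that grid
#' and Youden's J = max(TPR - FPR) is maximized over the swept thresholds.
#'
#' @param sdi an `sdi` (or plain 3-D array of densities).
#' @param gold logical gold-standard tract mask.
#' @param search logical search-volume mask (e.g. inclusion ∪ gold).
#' @param n_points number of FPR grid points (default 1000).
#' @return object of class `roc_curve`: data.frame `grid` (fpr, tpr),
#'   `swept` (threshold, fpr, tpr), `auc`, `youden_j`, `threshold_at_j`,
#'   `search_voxels`.
#' @export
roc_analysis <- function(sdi, gold, search, n_points = 1000L) {
  v <- if (inherits(sdi, "sdi")) sdi$data else sdi
  if (!any(search)) stop("undefined rates: empty search volume")
  pos <- gold & search
  neg <- search & !gold
  if (!any(pos) || !any(neg))
    stop("undefined rates: search volume must contain gold and non-gold voxels")
  vp <- v[pos]; vn <- v[neg]
  np <- length(vp); nn <- length(vn)
  thr <- sort(unique(c(vp, vn)))
  # cumulative counts above each threshold (strict >)
  tpr <- vapply(thr, function(t) sum(vp > t), numeric(1)) / np
  fpr <- vapply(thr, function(t) sum(vn > t), numeric(1)) / nn
  swept <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  # polyline in sweep order (threshold descending): the max threshold gives
  # (0, 0); the t -> -Inf anchor gives (1, 1).  Consecutive swept points are
  # joined linearly (vertical, horizontal, or -- under ties -- diagonal
  # segments), which reproduces the tie-corrected ROC exactly.
  fx <- c(rev(fpr), 1); ty <- c(rev(tpr), 1)
  grid_fpr <- seq(0, 1, length.out = n_points)
  i <- findInterval(grid_fpr, fx)      # last sweep point with fpr <= f
  grid_tpr <- vapply(seq_along(grid_fpr), function(k) {
    f <- grid_fpr[k]; j <- i[k]
    if (j >= length(fx)) return(ty[length(ty)])
    if (fx[j + 1] > fx[j])
      ty[j] + (ty[j + 1] - ty[j]) * (f - fx[j]) / (fx[j + 1] - fx[j])
    else ty[j]
  }, numeric(1))
  auc <- sum(diff(grid_fpr) * (head(grid_tpr, -1) + tail(grid_tpr, -1)) / 2)
  j <- tpr - fpr
  jbest <- which.max(j)
  structure(list(grid = data.frame(fpr = grid_fpr, tpr = grid_tpr),
                 swept = swept, auc = auc, youden_j = j[jbest],
                 threshold_at_j = thr[jbest],
                 search_voxels = sum(search)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, Youden J = %.3f at threshold %.4g (search volume %d voxels)\n",
              x$auc, x$youden_j, x$threshold_at_j, x$search_voxels))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$grid$fpr, x$grid$tpr, type = "l", xlab = "FPR",
                 ylab = "TPR", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' SDI threshold achieving a target false positive rate
#'
#' Returns the smallest distinct SDI value whose FPR (over search \\ gold,
#' strict >) does not exceed `target_fpr`.
#'
#' @param sdi an `sdi` or 3-D array.
#' @param gold,search logical masks.
#' @param target_fpr target FPR in [0, 1] (default 0.021, i.e. 2.1%).
#' @return the threshold (SDI intensity units).
#' @export
threshold_at_fpr <- function(sdi, gold, search, target_fpr = 0.021) {
  if (target_fpr < 0 || target_fpr > 1)
    stop("invalid argument: target_fpr must be in [0, 1]")
  v <- if (inherits(sdi, "sdi")) sdi$data else sdi
  neg <- search & !gold
  if (!any(neg)) stop("undefined rate: no non-gold voxels in the search volume")
  vn <- v[neg]; nn <- length(vn)
  thr <- sort(unique(as.vector(v[search])))
  fpr <- vapply(thr, function(t) sum(vn > t), numeric(1)) / nn
  ok <- which(fpr <= target_fpr)
  if (!length(ok))
    stop(sprintf("unreachable target FPR %g", target_fpr))
  thr[ok[1]]
}

#' Finalize binary tracts with a cross-subject median threshold
#'
#' Applies the median of the per-subject thresholds to every SDI and reports
#' the binary tracts and their volumes.
#'
#' @param sdis list of `sdi` objects (or 3-D arrays), one per subject.
#' @param thresholds per-subject SDI thresholds.
#' @param voxel_volume_mm3 voxel volume in mm^3 (taken from the first `sdi`
#'   affine if omitted).
#' @return list with `threshold` (the median), `masks` (list of logical
#'   arrays) and `volumes_cm3`.
#' @export
finalize_tracts <- function(sdis, thresholds, voxel_volume_mm3 = NULL) {
  if (length(sdis) < 1) stop("need >= 1 subject")
  if (is.null(voxel_volume_mm3)) {
    a <- sdis[[1]]$affine
    voxel_volume_mm3 <- abs(det(a[1:3, 1:3]))
  }
  thr <- median(thresholds)
  masks <- lapply(sdis, function(s) {
    v <- if (inherits(s, "sdi")) s$data else s
    m <- v > thr
    if (!any(m)) warning("empty final tract at the median threshold")
    m
  })
  vols <- vapply(masks, function(m) sum(m) * voxel_volume_mm3 / 1000,
                 numeric(1))
  list(threshold = thr, masks = masks, volumes_cm3 = vols)
}

#' Landmark distances of a binary tract
#'
#' The anterior tip (Meyer's-loop-apex analogue) is located automatically as
#' the centroid of tract voxels on the most anterior occupied coronal slice;
#' distances to the temporal-pole and occipital-pole landmarks are measured
#' along the anterior-posterior axis (|Δy|), the axis dissection-style
#' distances are reported on.
#'
#' @param tract logical tract mask.
#' @param affine 4x4 voxel-to-world matrix.
#' @param tp,op landmark world coordinates (mm).
#' @return list with `mla` (world mm), `mla_tp`, `mla_op`, `tp_op` (mm).
#' @export
measure_landmarks <- function(tract, affine, tp, op) {
  if (!any(tract)) stop("empty tract: cannot measure landmarks")
  idx <- which(tract, arr.ind = TRUE) - 1L
  w <- voxel_to_world(idx, affine)
  ymax <- max(w[, 2])
  tipvox <- w[w[, 2] == ymax, , drop = FALSE]
  mla <- colMeans(tipvox)
  list(mla = mla,
       mla_tp = abs(mla[2] - tp[2]),
       mla_op = abs(mla[2] - op[2]),
       tp_op = abs(tp[2] - op[2]))
}

#' Paired Wilcoxon signed-rank and paired t tests
#'
#' Two-sided tests of paired per-subject metrics.  Zero differences are
#' dropped (standard signed-rank convention); the signed-rank null is exact
#' for n <= 15 remaining pairs without ties and a normal approximation
#' otherwise.  All-zero differences yield a degenerate flag with p = 1.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 5).
#' @return list with `wilcoxon` (statistic, p_value, method), `t`
#'   (statistic, p_value), `n`, `degenerate`.
#' @export
paired_tests <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  if (length(values_a) < 5) stop("need >= 5 pairs")
  dd <- values_a - values_b
  if (all(dd == 0)) {
    return(list(wilcoxon = list(statistic = NA_real_, p_value = 1,
                                method = "degenerate"),
                t = list(statistic = 0, p_value = 1),
                n = length(dd), degenerate = TRUE))
  }
  nz <- dd[dd != 0]
  exact <- length(nz) <= 15 && !any(duplicated(abs(nz)))
  w <- suppressWarnings(wilcox.test(values_a, values_b, paired = TRUE,
                                    exact = exact, correct = !exact))
  tt <- t.test(values_a, values_b, paired = TRUE)
  list(wilcoxon = list(statistic = unname(w$statistic),
                       p_value = w$p.value,
                       method = if (exact) "exact" else "normal approximation"),
       t = list(statistic = unname(tt$statistic), p_value = tt$p.value),
       n = length(dd), degenerate = FALSE)
}

#' Dice similarity coefficient of two masks
#'
#' @param a,b logical arrays.
#' @return `2 |a ∩ b| / (|a| + |b|)` (1 if both are empty).
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
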