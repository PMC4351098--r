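#' Gradient-direction subsampling experiment
#'
#' Re-runs the CSD tracking pipeline on energy-minimal subsets of the
#' acquired directions and scores each subset's final binary tract against
#' the full-data final tract (the within-experiment gold standard):
#' sensitivity, specificity, Dice overlap, and the FPR obtained when the
#' full-data final SDI threshold is held fixed.  The harmonic order is
#' lowered automatically when a subset has fewer directions than SH
#' coefficients.
#'
#' @param dwi_full a `dwi_volume` with the complete scheme.
#' @param scheme_full its `gradient_scheme`.
#' @param counts integer vector of direction counts to test (each >= 6 and
#'   <= the available directions).
#' @param phantom the `phantom` the data were simulated from (supplies
#'   seed/target masks, landmarks and the probability map).
#' @param config a [run_config()] providing tracking/evaluation settings.
#' @return data.frame with one row per count (the full-data reference row
#'   included, labelled by the full direction count): n_directions, lmax,
#'   retained, sensitivity, specificity, dice, fpr_at_fixed_threshold.
#' @export
subsample_experiment <- function(dwi_full, scheme_full, counts, phantom,
                                 config = run_config()) {
  n_avail <- nrow(scheme_full$directions)
  if (any(counts > n_avail))
    stop("invalid argument: count exceeds available directions")
  if (any(counts < 6)) stop("invalid argument: counts must be >= 6")

  gold <- probability_to_mask(phantom$tract_probability_map,
                              config$gold_threshold)
  planes <- make_planes(gold, phantom$affine, phantom$landmarks$tp,
                        midline_x = config$phantom$midline_x)

  run_one <- function(dwi, scheme, lmax, track_seed) {
    brain <- brain_mask(dwi, scheme)
    tens <- fit_dti(dwi, scheme, mask = brain)
    incl <- brain & !is.na(tens$fa) & tens$fa > config$tracking$fa_threshold
    search <- incl | gold
    resp <- estimate_response(dwi, scheme, tens,
                              fa_cutoff = config$response_fa_cutoff,
                              lmax = lmax)
    fod <- csd_fit(dwi, scheme, resp, lmax = lmax, mask = incl)
    tp <- config$tracking
    tp$seed <- track_seed
    raw <- propagate(fod, phantom$seed_mask, incl, tp)
    filt <- filter_streamlines(raw, planes$waypoint, phantom$target_mask,
                               planes$exclusion, planes$termination)
    if (filt$retained < 1) {
      # heavily degraded data can retain nothing; score as an empty tract
      warning(sprintf("no streamline retained with %d directions; scoring an empty tract",
                      nrow(scheme$directions)))
      sdi <- structure(list(data = array(0, dim(incl)), n_streamlines = 0L,
                            affine = phantom$affine), class = "sdi")
    } else sdi <- compute_sdi(filt)
    list(sdi = sdi, search = search, retained = filt$retained)
  }

  lmax_for <- function(n) {
    l <- config$lmax
    while (l > 2 && sh_ncoef(l) > n) l <- l - 2
    l
  }

  base_seed <- derive_seed(config$seed, .stage_id["subsample"])
  full <- run_one(dwi_full, scheme_full, lmax_for(n_avail), base_seed)
  thr_full <- threshold_at_fpr(full$sdi, gold, full$search, config$target_fpr)
  ref_mask <- full$sdi$data > thr_full

  score <- function(run, n, lmax) {
    mask <- run$sdi$data > thr_full
    tp_ <- sum(mask & ref_mask); fn_ <- sum(!mask & ref_mask)
    fp_ <- sum(mask & !ref_mask & run$search)
    tn_ <- sum(!mask & !ref_mask & run$search)
    data.frame(n_directions = n, lmax = lmax, retained = run$retained,
               sensitivity = tp_ / (tp_ + fn_),
               specificity = tn_ / (tn_ + fp_),
               dice = dice_coefficient(mask, ref_mask),
               fpr_at_fixed_threshold = fp_ / (fp_ + tn_))
  }

  out <- list(score(full, n_avail, lmax_for(n_avail)))
  for (k in counts) {
    if (k == n_avail) { run <- full; lmax <- lmax_for(k) }
    else {
      sub <- subset_gradient_scheme(scheme_full, k)
      vol <- attr(sub, "volume_index")
      dwi_sub <- structure(list(data = dwi_full$data[, , , vol, drop = FALSE],
                                affine = dwi_full$affine, scheme = sub),
                           class = "dwi_volume")
      lmax <- lmax_for(k)
      run <- run_one(dwi_sub, sub, lmax, derive_seed(base_seed, k))
    }
    out[[length(out) + 1]] <- score(run, k, lmax)
  }
  res <- do.call(rbind, out)
  res[!duplicated(res$n_directions), , drop = FALSE]
}
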