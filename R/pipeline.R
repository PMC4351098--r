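#' Pipeline run configuration
#'
#' One configuration drives the whole workflow: phantom construction, DWI
#' simulation for `n_subjects` independent noise realizations ("subjects"),
#' DTI fitting, response estimation, CSD and/or ball-and-stick fitting,
#' mask construction, tracking, SDI accumulation and evaluation.  Every
#' stochastic stage derives its seed deterministically from the global seed
#' via [derive_seed()], so single stages can be re-run reproducibly.
#'
#' The default is the desk-scale study configuration: default phantom,
#' 30 directions at b = 3000, SNR 30, both models, 100 streamlines per seed
#' voxel, 5 subjects.
#'
#' @param phantom a [phantom_config()].
#' @param n_directions,b_value,n_b0 gradient scheme parameters.
#' @param s0,snr simulation parameters.
#' @param models character subset of c("csd", "ballstick").
#' @param lmax CSD maximum harmonic order.
#' @param response_fa_cutoff FA cutoff for response voxel selection.
#' @param n_sticks,mcmc ball-and-stick settings.
#' @param tracking a [tracking_params()].
#' @param n_subjects number of noise realizations.
#' @param gold_threshold probability threshold defining the gold mask.
#' @param target_fpr FPR at which per-subject thresholds are read off.
#' @param seed global seed.
#' @param out_dir optional output directory for on-disk artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_directions = 30L, b_value = 3000, n_b0 = 1L,
                       s0 = 100, snr = 30,
                       models = c("csd", "ballstick"),
                       lmax = 6L,
                       response_fa_cutoff = 0.6,
                       n_sticks = 2L,
                       mcmc = list(burn_in = 1000L, n_samples = 50L, thin = 25L),
                       tracking = tracking_params(streamlines_per_seed_voxel = 100L),
                       n_subjects = 5L,
                       gold_threshold = 0.1,
                       target_fpr = 0.021,
                       seed = 1L,
                       out_dir = NULL) {
  models <- match.arg(models, c("csd", "ballstick"), several.ok = TRUE)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# stage identifiers for seed derivation
.stage_id <- c(scheme = 1L, simulate = 2L, ballstick = 3L, track_csd = 4L,
               track_ballstick = 5L, subsample = 6L)

#' Run the full phantom study pipeline
#'
#' Executes simulate -> fit-dti -> fit-fod (both models) -> make-masks ->
#' track -> evaluate for every subject (noise realization) of the
#' configuration, then finalizes tracts with the cross-subject median
#' threshold and compares the models with paired statistics.  If
#' `config$out_dir` is set, per-stage artifacts (NIfTI volumes, gradient
#' tables, TCK tracks, CSV reports) and a manifest are written there.
#'
#' @param config a [run_config()].
#' @return object of class `or_eval_report`: `per_subject` data.frame
#'   (model, subject, AUC, Youden J, threshold, retained counts, final
#'   volume, landmark distances, anterior-tip error), `paired` list of
#'   paired tests (CSD vs ball-and-stick) per metric, `final` per-model
#'   finalization results, `phantom`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  t0 <- Sys.time()
  manifest <- list()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s +%5.1fs] %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(...)))
  }
  emit <- function(stage, files, params = list()) {
    manifest[[length(manifest) + 1]] <<- list(stage = stage, files = files,
                                              params = params)
  }

  scheme <- generate_gradient_scheme(cfg$n_directions, cfg$b_value, cfg$n_b0,
                                     seed = derive_seed(cfg$seed, .stage_id["scheme"]))
  phan <- build_or_phantom(cfg$phantom, seed = cfg$seed)
  log_stage("phantom", "tract %d voxels, %d seed voxels",
            sum(phan$tract_mask), sum(phan$seed_mask))

  gold <- probability_to_mask(phan$tract_probability_map, cfg$gold_threshold)
  planes <- make_planes(gold, phan$affine, phan$landmarks$tp,
                        midline_x = cfg$phantom$midline_x)

  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map_nifti(gold, phan$affine, file.path(out_dir, "gold_mask.nii.gz"))
    write_map_nifti(phan$tract_probability_map, phan$affine,
                    file.path(out_dir, "tract_probability.nii.gz"))
    emit("make-masks", c("gold_mask.nii.gz", "tract_probability.nii.gz"),
         list(gold_threshold = cfg$gold_threshold))
  }

  rows <- list()
  sdis <- list(csd = list(), ballstick = list())
  thresholds <- list(csd = numeric(0), ballstick = numeric(0))
  retained <- list(csd = integer(0), ballstick = integer(0))
  initiated <- integer(0)

  for (s in seq_len(cfg$n_subjects)) {
    dwi <- simulate_dwi(phan, scheme, s0 = cfg$s0, snr = cfg$snr,
                        seed = derive_seed(cfg$seed, .stage_id["simulate"], s))
    brain <- brain_mask(dwi, scheme)
    tens <- fit_dti(dwi, scheme, mask = brain)
    incl <- brain & !is.na(tens$fa) & tens$fa > cfg$tracking$fa_threshold
    if (!any(incl)) stop(sprintf("stage fit-dti failed for subject %d: empty inclusion mask", s))
    search <- incl | gold
    log_stage("fit-dti", "subject %d: inclusion %d voxels", s, sum(incl))

    if (!is.null(out_dir)) {
      pre <- file.path(out_dir, sprintf("subject%02d", s))
      write_dwi_nifti(dwi, pre)
      write_map_nifti(tens$fa, phan$affine, paste0(pre, "_fa.nii.gz"))
      write_map_nifti(tens$adc, phan$affine, paste0(pre, "_adc.nii.gz"))
      emit("simulate", basename(paste0(pre, c(".nii.gz", ".bvec", ".bval"))),
           list(subject = s, snr = cfg$snr))
      emit("fit-dti", basename(paste0(pre, c("_fa.nii.gz", "_adc.nii.gz"))),
           list(subject = s))
    }

    models <- list()
    if ("csd" %in% cfg$models) {
      resp <- estimate_response(dwi, scheme, tens,
                                fa_cutoff = cfg$response_fa_cutoff,
                                lmax = cfg$lmax)
      models$csd <- csd_fit(dwi, scheme, resp, lmax = cfg$lmax, mask = incl)
      log_stage("fit-fod", "subject %d: CSD done (response from %d voxels)",
                s, resp$n_voxels)
    }
    if ("ballstick" %in% cfg$models) {
      models$ballstick <- ballstick_fit(
        dwi, scheme, n_sticks = cfg$n_sticks, mcmc = cfg$mcmc,
        seed = derive_seed(cfg$seed, .stage_id["ballstick"], s), mask = incl)
      log_stage("fit-fod", "subject %d: ball-and-stick done (acc %.2f)",
                s, mean(models$ballstick$acceptance, na.rm = TRUE))
    }

    for (mn in names(models)) {
      tp <- cfg$tracking
      tp$seed <- derive_seed(cfg$seed, .stage_id[paste0("track_", mn)], s)
      raw <- propagate(models[[mn]], phan$seed_mask, incl, tp)
      filt <- filter_streamlines(raw, planes$waypoint, phan$target_mask,
                                 planes$exclusion, planes$termination)
      log_stage("track", "subject %d %s: %d initiated, %d retained",
                s, mn, filt$initiated, filt$retained)
      if (filt$retained < 1)
        stop(sprintf("stage track failed for subject %d (%s): no streamline retained", s, mn))
      sdi <- compute_sdi(filt)
      roc <- roc_analysis(sdi, gold, search)
      thr <- threshold_at_fpr(sdi, gold, search, cfg$target_fpr)

      sdis[[mn]][[s]] <- sdi
      thresholds[[mn]] <- c(thresholds[[mn]], thr)
      retained[[mn]] <- c(retained[[mn]], filt$retained)
      if (mn == "csd") initiated <- c(initiated, filt$initiated)
      rows[[length(rows) + 1]] <- data.frame(
        model = mn, subject = s, auc = roc$auc, youden_j = roc$youden_j,
        threshold = thr, initiated = filt$initiated,
        retained = filt$retained, search_voxels = roc$search_voxels)
      if (!is.null(out_dir)) {
        pre <- file.path(out_dir, sprintf("subject%02d_%s", s, mn))
        write_tck(filt, paste0(pre, ".tck"))
        write_map_nifti(sdi$data, phan$affine, paste0(pre, "_sdi.nii.gz"))
        emit("track", basename(paste0(pre, c(".tck", "_sdi.nii.gz"))),
             list(subject = s, model = mn,
                  initiated = filt$initiated, retained = filt$retained))
      }
    }
  }

  per_subject <- do.call(rbind, rows)

  # finalization and landmarks per model; anterior-tip errors are measured
  # against the true tract's anterior tip located by the same automated rule
  # (most anterior occupied slice), so voxelization affects truth and
  # estimate alike
  true_lm <- measure_landmarks(phan$tract_mask, phan$affine,
                               phan$landmarks$tp, phan$landmarks$op)
  final <- list()
  for (mn in names(sdis)) {
    if (!length(sdis[[mn]])) next
    fin <- finalize_tracts(sdis[[mn]], thresholds[[mn]])
    lm <- lapply(fin$masks, function(m) {
      if (!any(m)) return(list(mla = c(NA, NA, NA), mla_tp = NA, mla_op = NA,
                               tp_op = NA))
      measure_landmarks(m, phan$affine, phan$landmarks$tp, phan$landmarks$op)
    })
    sel <- per_subject$model == mn
    per_subject$final_volume_cm3[sel] <- fin$volumes_cm3
    per_subject$mla_tp[sel] <- vapply(lm, `[[`, numeric(1), "mla_tp")
    per_subject$mla_op[sel] <- vapply(lm, `[[`, numeric(1), "mla_op")
    per_subject$anterior_tip_error[sel] <- vapply(lm, function(l)
      abs(l$mla[2] - true_lm$mla[2]), numeric(1))
    final[[mn]] <- fin
  }

  paired <- NULL
  if (all(c("csd", "ballstick") %in% per_subject$model) && cfg$n_subjects >= 5) {
    g <- function(metric, model)
      per_subject[[metric]][per_subject$model == model]
    paired <- list(
      auc = paired_tests(g("auc", "csd"), g("auc", "ballstick")),
      youden_j = paired_tests(g("youden_j", "csd"), g("youden_j", "ballstick")),
      mla_tp = paired_tests(g("mla_tp", "csd"), g("mla_tp", "ballstick")))
  }

  report <- structure(list(per_subject = per_subject, paired = paired,
                           final = final, thresholds = thresholds,
                           phantom = phan, scheme = scheme, config = cfg,
                           manifest = manifest),
                      class = "or_eval_report")
  if (!is.null(out_dir)) {
    write.csv(per_subject, file.path(out_dir, "per_subject.csv"),
              row.names = FALSE)
    emit("evaluate", "per_subject.csv", list())
    mf <- vapply(manifest, function(m)
      sprintf("%s\t%s", m$stage, paste(m$files, collapse = ",")), character(1))
    writeLines(mf, file.path(out_dir, "manifest.tsv"))
    report$manifest <- manifest
  }
  report
}

#' @export
print.or_eval_report <- function(x, ...) {
  cat("phantom study report\n")
  agg <- stats::aggregate(cbind(auc, youden_j) ~ model, data = x$per_subject,
                          FUN = median)
  print(agg, row.names = FALSE)
  if (!is.null(x$paired)) {
    cat(sprintf("paired Wilcoxon (AUC): p = %.4f; paired t (MLA-TP): p = %.4f\n",
                x$paired$auc$wilcoxon$p_value, x$paired$mla_tp$t$p_value))
  }
  invisible(x)
}
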