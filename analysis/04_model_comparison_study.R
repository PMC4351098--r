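#!/usr/bin/env Rscript
# Stage 4: the full model-comparison study. Five independent noise
# realizations ("subjects") of the default phantom are simulated; CSD and
# ball-and-stick tractography are evaluated per subject by voxel-wise ROC
# against the atlas-style gold standard; final tracts use the cross-subject
# median SDI threshold at 2.1% FPR; models are compared with paired
# Wilcoxon signed-rank and paired t tests.

library(ortrack)

out <- "results/study"
report <- suppressWarnings(run_pipeline(run_config(seed = 1, out_dir = out)))
print(report)

ps <- report$per_subject
write.csv(ps, file.path(out, "per_subject.csv"), row.names = FALSE)

med <- function(metric, model) median(ps[[metric]][ps$model == model])
summary_tab <- data.frame(
  metric = c("AUC", "Youden J", "anterior-tip error (mm)", "MLA-TP (mm)",
             "final volume (cm^3)", "retained streamlines"),
  csd = c(med("auc", "csd"), med("youden_j", "csd"),
          med("anterior_tip_error", "csd"), med("mla_tp", "csd"),
          med("final_volume_cm3", "csd"), med("retained", "csd")),
  ballstick = c(med("auc", "ballstick"), med("youden_j", "ballstick"),
                med("anterior_tip_error", "ballstick"), med("mla_tp", "ballstick"),
                med("final_volume_cm3", "ballstick"), med("retained", "ballstick")))
write.csv(summary_tab, file.path(out, "model_medians.csv"), row.names = FALSE)

cat("\nper-model medians over 5 noise realizations:\n")
print(summary_tab, row.names = FALSE, digits = 3)

cat("\npaired CSD vs ball-and-stick statistics (n = 5):\n")
for (metric in names(report$paired)) {
  p <- report$paired[[metric]]
  cat(sprintf("  %-10s Wilcoxon signed-rank p = %.4f (%s); paired t p = %.4f\n",
              metric, p$wilcoxon$p_value, p$wilcoxon$method, p$t$p_value))
}

cat(sprintf("\nfindings: CSD median AUC %.3f vs ball-and-stick %.3f;\n",
            med("auc", "csd"), med("auc", "ballstick")))
cat(sprintf("anterior tip reached within %.1f mm (CSD) vs %.1f mm (B&S) of the true tip.\n",
            med("anterior_tip_error", "csd"),
            med("anterior_tip_error", "ballstick")))
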