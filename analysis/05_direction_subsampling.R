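#!/usr/bin/env Rscript
# Stage 5: dependence of CSD tractography on the number of diffusion
# directions. Energy-minimal subsets of the 30-direction acquisition are
# re-tracked and the final binary tract is scored against the full-data
# result (sensitivity, specificity, Dice, and FPR at the fixed full-data
# SDI threshold).

library(ortrack)

out <- "results/subsampling"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

cfg <- run_config(seed = seed)
phantom <- build_or_phantom(cfg$phantom, seed = seed)
scheme <- generate_gradient_scheme(cfg$n_directions, cfg$b_value, cfg$n_b0,
                                   seed = derive_seed(seed, 1))
dwi <- simulate_dwi(phantom, scheme, s0 = cfg$s0, snr = cfg$snr,
                    seed = derive_seed(seed, 2, 1))

tab <- suppressWarnings(
  subsample_experiment(dwi, scheme, c(8, 12, 20, 30), phantom, cfg))
write.csv(tab, file.path(out, "subsampling.csv"), row.names = FALSE)

cat("direction-subsampling results (reference = full 30-direction tract):\n")
print(tab, row.names = FALSE, digits = 3)

lo <- tab[tab$n_directions == min(tab$n_directions), ]
cat(sprintf("\nfindings: at %d directions the FPR at the fixed threshold rises to %.1f%%\n",
            lo$n_directions, 100 * lo$fpr_at_fixed_threshold))
cat(sprintf("and Dice overlap with the full-data tract falls to %.2f,\n", lo$dice))
cat("while the full 30-direction re-run reproduces itself exactly.\n")
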