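#!/usr/bin/env Rscript
# Stage 1: build the bent-loop optic-radiation phantom and simulate one
# 30-direction, b = 3000 s/mm^2 DWI acquisition at SNR 30.
# Writes NIfTI + FSL gradient tables + a plain-text truth sidecar under
# results/data/.

library(ortrack)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scheme <- generate_gradient_scheme(30, 3000, 1, seed = derive_seed(seed, 1))
phantom <- build_or_phantom(phantom_config(), seed = seed)
print(scheme)
print(phantom)

dwi <- simulate_dwi(phantom, scheme, s0 = 100, snr = 30,
                    seed = derive_seed(seed, 2, 1))
write_dwi_nifti(dwi, file.path(out, "subject01"))
write_map_nifti(phantom$tract_probability_map, phantom$affine,
                file.path(out, "tract_probability.nii.gz"))
write_map_nifti(phantom$tract_mask, phantom$affine,
                file.path(out, "tract_truth.nii.gz"))
write_map_nifti(phantom$seed_mask, phantom$affine,
                file.path(out, "seed_mask.nii.gz"))
write_map_nifti(phantom$target_mask, phantom$affine,
                file.path(out, "target_mask.nii.gz"))

lm <- phantom$landmarks
writeLines(c(
  sprintf("seed: %d", seed),
  sprintf("voxel_size_mm: %g", phantom$voxel_size),
  sprintf("apex_world_mm: %g %g %g", lm$apex[1], lm$apex[2], lm$apex[3]),
  sprintf("tp_world_mm: %g %g %g", lm$tp[1], lm$tp[2], lm$tp[3]),
  sprintf("op_world_mm: %g %g %g", lm$op[1], lm$op[2], lm$op[3]),
  sprintf("tract_voxels: %d", sum(phantom$tract_mask)),
  sprintf("seed_voxels: %d", sum(phantom$seed_mask))),
  file.path(out, "phantom_truth.txt"))

cat(sprintf("\nwrote DWI (%d volumes) and truth maps to %s\n",
            length(scheme$b_values), out))
cat(sprintf("true anterior tip (apex) at y = %.1f mm; MLA-TP would be %.1f mm\n",
            lm$apex[2], lm$tp[2] - lm$apex[2]))
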