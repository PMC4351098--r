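# ortrack

Probabilistic tractography of the optic radiation compared across two
fiber-orientation models — constrained spherical deconvolution (CSD) and
the ball-and-stick (B&S) multi-compartment model — on a synthetic
diffusion-MRI phantom with a Meyer's-loop-style anterior hairpin.

The optic radiation (OR) runs from the lateral geniculate nucleus (LGN) to
primary visual cortex (V1) and makes a sharp anterior detour (Meyer's loop)
whose extent matters for temporal-lobe surgery planning. Clinical DWI
protocols are short (here: 30 directions, b = 3000 s/mm², 2.5 mm isotropic
voxels), which stresses fiber-orientation estimation exactly where the OR is
hardest to track. This package reimplements, at desk scale on simulated
phantoms, the complete analysis needed to compare how well the two models
recover such a tract: multi-tensor DWI simulation with Rician noise, DTI
maps, CSD and MCMC ball-and-stick fiber-orientation estimation,
probabilistic streamline propagation under atlas-style mask logic,
streamline-density images (SDI), and ROC/Youden/threshold/landmark
evaluation with paired statistics. It is aimed at method developers who
want a controlled, fully synthetic testbed where the ground truth tract,
its anterior tip, and the acquisition are all known by construction.

## Models

Per voxel, the DW signal is simulated from a multi-tensor forward model

    S(g, b) = S₀ [ f_iso e^(−b d_iso) + Σₖ fₖ e^(−b gᵀDₖg) ],

with Rician noise of σ = S₀/SNR on the complex signal. The two estimators
under comparison:

* **CSD** — the signal is deconvolved by a measured single-fiber response
  in the real even spherical-harmonic basis (lmax = 6, 28 coefficients),
  with an iterative soft non-negativity constraint on a 300-direction grid
  (amplitudes below τ = 0.1 × mean initial amplitude are penalized until
  the constraint set stabilizes). The resulting fiber orientation
  distribution (FOD) is sampled directly during tracking.
* **Ball-and-stick** — S = S₀[(1 − Σfₖ)e^(−bd) + Σₖ fₖ e^(−bd (gᵀvₖ)²)]
  fitted per voxel by Metropolis-within-Gibbs MCMC (adaptive random-walk
  proposals; conjugate inverse-gamma noise-variance updates; 1000 burn-in,
  50 kept draws at thinning 25). Tracking draws one posterior sample per
  step and follows the admissible stick nearest the incoming direction.

Tracking uses the clinical-protocol parameters: 0.2 mm steps, a 0.3 mm
radius-of-curvature cutoff (per-step cone of 2·asin(step/2R) ≈ 38.9°), an
FA > 0.1 inclusion mask, bidirectional growth from jittered seed positions.
Streamlines must pass a waypoint slice 60 mm posterior to the temporal pole
(TP) and reach the V1 target while avoiding an exclusion plane 20 mm
posterior to the TP; they are truncated at a midline sagittal plane. SDIs
are per-voxel fractions of retained streamlines (binary visitation).
Evaluation sweeps every distinct SDI value, interpolates TPR onto 1000
equally spaced FPR values, reports AUC and Youden's J, thresholds each SDI
at 2.1% FPR, binarizes at the cross-subject median threshold, and measures
tract volume and anterior-tip (MLA), MLA–TP and MLA–OP distances along the
anterior–posterior axis.

## Worked example

```r
library(ortrack)

phantom <- build_or_phantom(phantom_config(), seed = 1)
scheme  <- generate_gradient_scheme(30, 3000, 1, seed = derive_seed(1, 1))
dwi     <- simulate_dwi(phantom, scheme, s0 = 100, snr = 30,
                        seed = derive_seed(1, 2, 1))

brain     <- brain_mask(dwi, scheme)
tensor    <- fit_dti(dwi, scheme, mask = brain)
inclusion <- brain & !is.na(tensor$fa) & tensor$fa > 0.1
response  <- estimate_response(dwi, scheme, tensor, fa_cutoff = 0.6)
fod       <- csd_fit(dwi, scheme, response, lmax = 6, mask = inclusion)

gold   <- probability_to_mask(phantom$tract_probability_map, 0.1)
planes <- make_planes(gold, phantom$affine, phantom$landmarks$tp, midline_x = 10)
raw    <- propagate(fod, phantom$seed_mask, inclusion,
                    tracking_params(streamlines_per_seed_voxel = 100, seed = 7))
kept   <- filter_streamlines(raw, planes$waypoint, phantom$target_mask,
                             planes$exclusion, planes$termination)
sdi    <- compute_sdi(kept)
roc    <- roc_analysis(sdi, gold, inclusion | gold)
print(roc)
```

which prints (seed-exact):

```
ROC: AUC = 0.705, Youden J = 0.405 at threshold 0 (search volume 3003 voxels)
```

(two of the 19 seed voxels fall below the FA threshold under this noise
realization and are skipped with a warning). Ranking voxels by streamline
density separates true tract from non-tract search voxels with AUC 0.71,
and the best single threshold gains 40 percentage points of sensitivity
over its false-positive rate. The same subject evaluated with the
ball-and-stick model gives AUC 0.644 and J = 0.288; over five noise
realizations the medians are AUC 0.702 (CSD) vs
0.644 (B&S) and Youden J 0.398 vs 0.288, both models placing the recovered
anterior tip at the true tract tip (MLA-TP 25 mm vs the 27.5 mm
construction truth, a one-voxel quantization). The numbered scripts under
`analysis/` run these stages end to end and write their tables under
`results/`.

## Coefficient conventions

FOD spherical-harmonic coefficients are stored in 4-D NIfTI volumes with
degrees l = 0, 2, …, lmax ascending and m = −l…+l within each degree
(sine terms for m < 0, zonal at m = 0, cosine for m > 0), orthonormal on
the sphere. Streamlines are written as MRtrix TCK (Float32LE); masks and
maps as NIfTI-1 with the phantom's RAS+ affine; gradient tables as
FSL-dialect `bvec`/`bval` text files.
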