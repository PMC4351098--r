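---
title: "Phantom-based comparison of CSD and ball-and-stick tractography of the optic radiation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based comparison of CSD and ball-and-stick tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what is
simulated, what is estimated, which parameters matter, and where the design
was genuinely open.

## The problem

The optic radiation (OR) connects the lateral geniculate nucleus (LGN) to
primary visual cortex (V1). Its anterior portion, Meyer's loop, doubles
back on itself within a few centimetres — a geometry that probabilistic
tractography handles with difficulty, and whose recovered anterior extent
(the MLA landmark) is the accepted yardstick for comparing OR tractography
methods. The package provides a fully synthetic testbed for that
comparison: a phantom whose tract geometry, fiber orientations, landmarks
and acquisition are known exactly, so the two fiber-orientation models
under study — constrained spherical deconvolution (CSD) and the
ball-and-stick (B&S) model — can be scored against construction truth
rather than against an uncertain anatomical reference.

## The phantom and what it does (and does not) emulate

`build_or_phantom()` voxelizes a fan of hairpin curves: an anterior limb
rises from the seed (LGN analogue), a semicircular arc of radius 7.5 mm
turns 180 degrees over the apex (the Meyer's-loop-tip analogue), and a
posterior limb fans out in depth and width to the target (V1 analogue). A
straight second tube crosses the fan body so that crossing-fiber behaviour
is exercised. Default grid: 40 x 50 x 20 voxels at 2.5 mm isotropic — the
emulated clinical voxel size on a reduced field of view. World coordinates
are NIfTI RAS+ (+y anterior), voxel (0,0,0) centred at the origin; all
geometric defaults are artifact choices of this package, set once:
apex at y = 87.5 mm, TP landmark at y = 115 mm (so the true MLA–TP
distance, 27.5 mm, sits in the range dissection studies report), OP at
y = 2.5 mm, seed limb base at y = 60 mm, target at y = 12.5 mm, midline
plane at x = 10 mm.

Tract voxels hold a fiber compartment (eigenvalues 1.7/0.3/0.3 x 10⁻³
mm²/s, volume fraction 0.7 — typical white-matter literature values) plus a
CSF-like isotropic remainder (d = 3.0 x 10⁻³ mm²/s). Where the crossing
tube overlaps the fan, the two populations split the fiber fraction
(0.35 + 0.35). A tissue envelope (the tract system dilated by 6 mm) is
filled with grey-matter-like isotropic material (d = 0.8 x 10⁻³ mm²/s);
outside it there are no spins, so the background is pure Rician noise, as
in magnitude MRI outside the head. The atlas surrogate is the binary truth
blurred with a 1-voxel Gaussian and max-normalized — mimicking the
inter-subject variability of a probabilistic atlas — and thresholded at
0.1 for the gold mask, the convention for a ten-brain atlas where voxels
belonging to more than one brain are retained.

The simulator reproduces the signal statistics that matter for
fiber-orientation estimation: the multi-tensor forward model, b0
referencing, and Rician noise (magnitude of the complex signal plus
Gaussian noise of σ = s0/SNR, SNR 30 at b0 by default). It deliberately
omits eddy currents, susceptibility distortion, motion, T2 partial-volume
effects and anatomy beyond the tract system. Passing tests therefore
demonstrate correctness of the estimation and evaluation machinery and the
models' *relative* behaviour on known geometry; they do not certify
performance on real, artifact-laden data, and absolute AUC values on the
phantom are not comparable to values measured against a real atlas.

## Estimation

**DTI.** Log-linear weighted least squares (two iterations, weights equal
to the squared predicted signal). Intensities at or below zero — possible
under Rician noise — are floored at the smallest positive value in the
voxel's own series before the log. Negative fitted eigenvalues are clamped
to zero before FA, so FA stays in [0, 1]; ADC is the unclamped eigenvalue
mean.

**Response and CSD.** The single-fiber response is the zonal (m = 0)
spherical-harmonic fit of b0-normalized signals from high-FA voxels, each
voxel reoriented so its principal eigenvector maps to +z. The default
selection cutoff is FA > 0.7; the pipeline configuration uses 0.6 because
the phantom's fiber voxels carry a 30% CSF-like fraction that depresses
their fitted FA — the cutoff is a selection rule, not a claim about pure
fiber anisotropy. CSD solves, per voxel, a least-squares deconvolution in
the real even SH basis (lmax 6 by default, 28 coefficients; initialisation
at lmax <= 4, which stays overdetermined with 30 directions) followed by
the iterative soft constraint: amplitudes on a 300-direction Fibonacci
grid below τ = 0.1 x the mean initial amplitude are penalized with weight
λ (user default 1) until the constrained set stabilizes or 50 iterations
pass. Internally λ is normalized so the data and penalty blocks have
commensurate row scales, times a factor 5 chosen so that λ = 1 suppresses
negative lobes to within about 10% of the mean amplitude on noiseless
data; under noise the soft constraint still allows small excursions, which
is inherent to the soft formulation.

**Ball-and-stick.** Metropolis-within-Gibbs per voxel: component-wise
random-walk updates for s0, the shared diffusivity d (uniform prior on
10⁻⁵–10⁻² mm²/s), stick fractions (uniform on the simplex) and stick
orientations (sin θ area prior), plus a conjugate inverse-gamma Gibbs
update for the Gaussian noise variance. Proposal scales adapt during
burn-in toward 0.3–0.5 acceptance. Defaults: 2 sticks, 1000 burn-in, 50
kept samples at thinning 25 — conventional settings, not values recovered
from any publication. The Gaussian (not Rician) likelihood matches common
practice and keeps the sampler simple; at SNR 30 the bias is negligible
for the quantities compared here.

## Tracking

Fixed-step Euler integration (0.2 mm steps — an eighth of a voxel, so
higher-order integrators would add nothing), bidirectional from uniformly
jittered intra-voxel seed positions. The curvature cutoff is stated as a
radius (0.3 mm); it is formalized as the per-step cone of the arc–chord
relation, 2·asin(step/2R) ≈ 38.9° at the defaults. The initial direction
is sampled from the model on the full sphere and the first step follows it
exactly, so the two growth halves meet at the seed within the cone. CSD
steps rejection-sample the trilinearly interpolated FOD amplitude inside
the cone (cap 500 trials, then the streamline terminates); directions with
amplitude below 0.1 x the local peak are inadmissible, which prevents
tracking along spurious deconvolution side lobes and the noise floor —
the lmax-6 projection of even a perfect delta has side lobes of about 9%
relative amplitude. B&S steps draw one posterior sample at the nearest
voxel and follow the admissible stick (posterior mean fraction >= 0.05)
closest to the incoming direction. Streamlines terminate on leaving the
FA > 0.1 inclusion mask, exceeding 250 mm, or exhausting trials. The
FA threshold *defines* the inclusion mask, and growth is bidirectional —
two points the clinical tools leave ambiguous; both choices are asserted
by the tests.

Desk scale: tests and the study configuration launch 100 streamlines per
seed voxel (the emulated protocol's 5000 remains the `tracking_params()`
default for users who want it); with the default phantom's ~19 seed
voxels a full two-model, five-realization study runs in about two minutes
on one CPU.

## Evaluation

The streamline-density image (SDI) counts each retained streamline at most
once per voxel, normalized by the retained count. ROC analysis sweeps
every distinct SDI value as a strict (>) threshold over a search volume
(inclusion ∪ gold by default — the package exposes the search mask as an
explicit argument because "within the inclusion mask" and "union of tracts
and atlas" are both defensible and differ); TPR = hit fraction of gold,
FPR = hit fraction of search∖gold. TPR is interpolated onto 1000 equally
spaced FPR values along the sweep-ordered polyline — linear between
adjacent swept points, anchored at (0,0) (the maximum threshold) and (1,1)
(threshold −∞). That polyline reproduces the tie-corrected ROC exactly:
its trapezoid equals the Mann–Whitney concordance probability, which the
tests verify against brute-force enumeration on every instance with <= 15
search voxels. Interpolating after collapsing duplicate FPR values
instead (e.g. `approx(ties = max)`) cuts corners *above* the staircase
and systematically inflates AUC — the reason the polyline construction is
spelled out here.

Per-subject SDI thresholds are read off at FPR <= 2.1% (the smallest
distinct SDI value satisfying the bound; ties resolve to the lowest
threshold); the *median* threshold across subjects binarizes every SDI,
mirroring the cross-patient convention, and volumes are suprathreshold
voxel counts times voxel volume. The anterior tip (MLA) is located
automatically as the centroid of the most anterior occupied coronal
slice — a reproducible proxy for an expert reading — and MLA–TP, MLA–OP,
TP–OP distances are anterior–posterior (|Δy|) distances, the axis on which
dissection-style measurements are quoted. The anterior-tip *error* is
measured against the true tract mask's own MLA located by the same rule,
so voxelization affects truth and estimate alike; measuring against the
continuous apex point instead would penalize any model that correctly
fills the tube around the apex by half a tube width. Paired comparisons
use the Wilcoxon signed-rank test (zero differences dropped, exact null
for n <= 15 without ties, normal approximation otherwise; all-zero
differences return a degenerate flag with p = 1) and the paired t-test,
via the standard base-R implementations; the exact signed-rank null is
cross-checked in the tests by enumerating all 2⁶ sign assignments.

The direction-subsampling experiment removes directions greedily (always
deleting the direction contributing most electrostatic energy), lowers
lmax when a subset has fewer directions than SH coefficients, re-runs the
CSD pipeline, and scores the re-run's final tract against the full-data
final tract at the *fixed* full-data threshold — sensitivity, specificity,
Dice, and the FPR inflation that signals degraded angular information.

## Seeds and determinism

Every stochastic stage draws its seed from the global seed via
`derive_seed(seed, stage, subject)` (a fixed affine map modulo a large
prime, always below 2³¹), so single stages can be re-run in isolation and
whole runs are bit-identical for a fixed seed. The C++ kernels use R's own
RNG, so determinism holds across the R/C++ boundary. One deliberate
tie-break: the phantom's nearest-curve assignment uses first-wins ordering
(`max.col(ties.method = "first")`) because the default random tie-breaking
would silently consume RNG state and break reproducibility.

## Known limitations

* The soft CSD constraint bounds negative lobes only approximately under
  noise; a hard-constrained (quadratic-programming) variant would be
  stricter and slower.
* The B&S likelihood is Gaussian; at SNR well below ~10 the Rician bias
  would matter.
* The rejection-sampling envelope for FOD amplitudes uses 1.1 x the
  maximum over the eight surrounding voxel maxima; trilinear interpolation
  can in principle exceed a single voxel's grid maximum slightly, so the
  sampler is very mildly biased near envelope-saturating peaks.
* Affine registration is consumed, never estimated (`resample_affine()`
  resamples under a given transform only), and no EPI artifact model is
  included.
* The phantom's "subjects" are noise realizations of one geometry;
  inter-subject anatomical variability is represented only through the
  blurred probability map.
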