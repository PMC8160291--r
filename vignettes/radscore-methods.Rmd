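---
title: "radscore: methods, modelling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radscore: methods, modelling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radscore)
```

# What this package computes

radscore is a reference implementation of a two-modality MRI radiomics
workflow for predicting tumor progression/recurrence (P/R): fuzzy c-means
lesion segmentation on the contrast-enhanced T1-weighted channel, affine
mapping of the mask onto the T2-weighted channel, extraction of 107
radiomic features per modality (214 per patient), Gaussian-kernel SVM risk
scoring with sequential forward feature selection under repeated
stratified 10-fold cross-validation, and ROC / Kaplan–Meier / Cox
evaluation. Because clinical imaging cohorts of this kind are private, the
package ships a first-class synthetic cohort generator; every downstream
stage is developed and tested against it.

# The synthetic world

`generate_cohort()` states the world the analysis assumes. Its defaults
are fixed once and are not free knobs of the test suite.

**Imaging.** Each patient gets a pair of co-registered volumes on a
32 × 32 × 10 grid with 1 × 1 × 5 mm voxels (thick axial slices, as in
routine clinical T2/CE-T1 protocols). The lesion is a 10 mm-radius sphere
in world coordinates (an ellipsoid in voxels). Inside the mask the
intensity is `background + contrast` modulated by two fields:

* a Gaussian random field (correlation length 2 voxels, FFT convolution)
  passed through the monotone sinh–arcsinh transform
  `sinh(asinh(z) + eps)`, whose parameter `eps` controls skewness. The
  high-risk class plants `eps = 1.2` (plus per-patient N(0, 0.25²) jitter)
  against 0 for low risk. A skewing transform was chosen because the
  discriminative features of interest (GLCM cluster shade / prominence)
  are third/fourth-moment statistics;
* a coarser field (3× correlation length) quantized into plateaus —
  6 levels for low risk, 3 for high risk — which drives gray-level
  size-zone structure (fewer, larger equal-intensity zones for the
  high-risk class).

The T2-like channel is an independent texture realization with identical
geometry, mimicking co-registered sequences that share anatomy but not
noise. Amplitudes (contrast 100, texture 20, plateaus 30, noise SD 5 over
background 20) keep the lesion unambiguously hyperintense — deliberately
easy for segmentation, so a Dice ≥ 0.90 test establishes correctness of
the algorithm, not robustness to low contrast. Not emulated: MR physics,
bias fields, partial-volume effects, scanner heterogeneity (the emulated
study pooled 1.5 T and 3 T without harmonization), or lesions touching
anatomy. A green end-to-end test therefore demonstrates that the
pipeline's statistical machinery works on data with the assumed structure,
not that it transfers to clinical images.

**Covariates and outcomes.** Sex, age, resection extent and bone invasion
are drawn to match the emulated cohort's margins (43/128 male, ~73% gross
total resection, ~12% bone invasion); ADC is Gaussian with class means
0.865 / 0.785 (SD 0.08, ×10⁻³ mm²/s) so group medians bracket the 0.825
decision cutoff. ADC is simulated directly as a covariate — in the
emulated design it is measured manually outside the radiomics model. Time
to P/R is exponential with hazard

```
h = h0 * exp(beta_bone * bone + beta_adc * 1[ADC < 0.825] + beta_texture * latent)
```

where `latent` is the standardized per-patient skewness parameter actually
planted in the images. Censoring is uniform over 14–149 months (the
printed follow-up range); ties resolve as events. The study reports no
effect sizes linking texture to outcome, so the betas are free parameters
of the synthetic world — log 3, log 2.5 and 0.9 — and only *recovery* of
planted effects is claimed, not the published hazard ratios. The baseline
hazard 7.0 × 10⁻⁴/month was solved once by Monte Carlo (n = 20,000) so the
expected event fraction is ≈ 0.148 (19/128), the one calibration the
cohort structure prescribes.

# Segmentation

FCM runs per axial slice inside the operator's seed box (the box and the
first/last lesion slices are operator inputs; the pipeline derives them
from the truth mask with 4 voxels of in-plane padding). Choices the
source description leaves open, fixed here: K = 2 clusters, fuzziness
m = 2, centroid initialization at the 0.25/0.75 intensity quantiles
(deterministic), convergence when the largest centroid move falls below
1e-5 of the data range (a *relative* tolerance, which makes the whole
segmentation invariant to positive affine intensity rescaling — a tested
property), 200-iteration cap. The brighter cluster is the lesion;
membership is binarized at 0.5. Post-processing keeps the largest
26-connected component, then fills holes in 3D (6-connected background)
and per-slice in 2D, since 5 mm slices make genuinely 3D holes rare.
Manual correction of failed segmentations is out of scope; an empty mask
raises a classed error and external mask files can be supplied instead.
One sharp edge is inherited from the operator contract: a seed-box slice
range that includes lesion-free slices makes FCM hallucinate a bright
cluster in pure noise on those slices (clustering is relative), degrading
the mask — the slice range must be the slices containing the lesion.

Mask mapping onto T2 composes the two voxel-to-world affines, resamples
with trilinear interpolation and re-binarizes at 0.5. Tests cover
identity, integer translations, 90° rotations and rigid round-trips.

# Feature set

The "107 per modality" count is realized as the de-facto standard
decomposition 14 shape + 18 first-order intensity + 24 GLCM + 16 GLRLM +
16 GLSZM + 5 NGTDM + 14 GLDM, the unique standard split consistent with
both "32 first-order" and "75 textural". Conventions:

* **Discretization**: fixed bin count (32), per modality per lesion;
  `level = floor((x − min)/(max − min) · N) + 1`, max → N. Bin-count
  discretization makes all texture features invariant to positive affine
  intensity rescaling (tested); raw-intensity statistics (mean, energy…)
  naturally are not.
* **Geometry**: texture in 3D, distance 1, the 13 unique direction
  offsets, features averaged over directions with at least one valid
  pair; zones/dependences use 26-connectivity; no isotropic resampling by
  default (none is reported in the emulated protocol).
* **GLDM**: dependence size = 1 + number of 26-neighbours within α = 0
  of the centre level (centre counted, sizes start at 1).
* **Degenerate moments**: skewness and kurtosis of a constant region are
  reported as 0; GLCM correlation of a single-level region is 1.
* **Shape**: mesh volume and surface area come from a marching-tetrahedra
  triangulation at iso-level 0.5 of the Gaussian-smoothed (σ = 0.8 voxel)
  mask indicator. Meshing the raw binary staircase overestimates a
  sphere's area by ~25%; with smoothing, benchmark errors on analytic
  spheres/ellipsoids are ≈ −2% (area), ≈ −5% (volume), < 1% (sphericity).
  Smoothing biases thin structures; masks too small to survive it fall
  back to the binary mesh. Axis lengths are 4·√λ of the coordinate
  covariance eigenvalues.

Every matrix family is verified against an independent brute-force oracle
(plain R loops over voxels, written from the definitions) to 10⁻⁶
relative on random phantoms; the worked toy examples (cluster shade 2/27
on `[1,1,1,2]`, size-zone non-uniformity 1 and 2 on enumerated lattices)
are asserted exactly.

# SVM scoring and feature selection

The score is the kernel expansion `f(x) = Σ w_n y_n G(x_n, x) + b` with
`G(x_n, x) = exp(−‖x_n − x‖²)`. No kernel width appears in that
expression, so the width is fixed at 1 and features are z-scored with
training-set parameters first — that is what makes a unit width
meaningful. The box constraint C defaults to 1 (unstated in the source
description; configurable). The dual is solved by a deterministic
Platt-style SMO in C++; the two-point problem is checked against the
closed-form dual solution and KKT conditions (0 ≤ w ≤ C, Σ w y = 0) hold
by construction.

Forward selection adds, per iteration, the candidate maximizing the
cross-validated objective on identical fold assignments (ties break to
the lower feature index), and stops below a 10⁻⁶ improvement or at 4
features (the emulated analysis selected exactly four). "Repeated 1,000
times" is interpreted as repeated random fold assignments of the 10-fold
CV; the pipeline default is 50 repeats for desk runtime (1,000 via
config), and the heavy test-suite runs use 1–10 repeats, documented where
they do. A compiled batched evaluator accelerates the candidate loop; its
equality with the reference `cv_objective()` path is itself under test.

Two deliberate decisions need flagging:

* **Selection objective**: the design default for `cv_objective()` is CV
  accuracy, but the *pipeline* config defaults to the AUC objective. At
  the cohort's ~15% prevalence the accuracy baseline is the 85% majority
  rate; in development runs no candidate cleared the 10⁻⁶ improvement
  threshold and selection degenerated to flat scores. AUC is prevalence-
  free and matches the evaluation metric. Accuracy remains one config
  switch away.
* **Cross-validated scores**: reported per-patient scores come from
  models not trained on that patient (out-of-fold), with refit-on-all as
  an option — whether the emulated study did likewise is unstated, and
  resubstitution scores are optimistic.

A caveat the permutation analysis makes concrete: feature selection runs
on the full cohort, *outside* the scoring cross-validation. Under
label permutation, re-running selection and then CV-scoring still yields
AUCs of 0.6–0.86 at n = 128 with 214 candidates — pure selection
optimism. The end-to-end test therefore uses the standard permutation
null (fixed scores, permuted labels); absolute AUCs from this pipeline
carry the same caveat as the emulated analysis.

# Evaluation statistics

AUC is the normalized Mann–Whitney U with ties counted ½ (equals the
trapezoidal ROC area; both are computed and compared in tests). The
cutoff maximizes Youden's J with the "positive when score > cutoff"
convention; J-ties break toward higher specificity. Group tables use
chi-square *without* continuity correction — this reproduces the printed
p = 0.007 for the resection 2 × 2 table ([[9, 84], [10, 25]]), where the
Yates-corrected value would be 0.016 — with Fisher's exact test when any
expected cell is below 5. Survival uses the product-limit estimator,
log-rank test and Efron-tie Cox models via the survival package, with the
univariate p < 0.05 gate before the multivariate fit. ICC is fixed to the
two-way random-effects, absolute-agreement, single-rater form ICC(2,1);
the form is unstated in the source description. The combined SVM + ADC
model is a logistic combination scored by its linear predictor — the
combination rule behind the published combined AUC is unstated, and this
choice is documented rather than claimed.

# Numerical and engineering notes

* Determinism: every stochastic step takes a seed; derived seeds stay in
  32-bit range; the RNG state is restored after each seeded block. Two
  pipeline runs with the same config are byte-identical.
* Entropies use log2 with an epsilon guard; GLCM MCC clamps the second
  eigenvalue into [0, 1]; NGTDM coarseness of a flat region is capped at
  10⁶.
* The SMO tolerance is 10⁻³ (libsvm-style) for CV work; tighter
  tolerances are used where tests compare against closed forms.
* NIfTI-1 I/O is implemented minimally in-package (no R NIfTI reader is
  available in the supported dependency set): little-endian single-file
  .nii/.nii.gz, sform affine, float64 volumes, uint8 masks; verified
  interoperable with nibabel.
* Config files are JSON (lossless round-trip); one run directory per
  invocation with the resolved config frozen inside.

# Known limitations

* The phantom is statistically, not physically, realistic; segmentation
  results on it say nothing about low-contrast or infiltrative lesions.
* Surface-area smoothing biases very thin (1–2 voxel) structures; the
  anisotropic 5 mm axis makes z-direction surface estimates coarse.
* Feature selection outside CV inflates absolute AUCs (quantified above).
* The accuracy objective degenerates under strong class imbalance; the
  pipeline defaults to AUC for that reason.
* Cox models accept numeric covariates only (factors must be coded 0/1
  by the caller); perfect separation is reported as non-convergence.
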