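# radscore

Pre-operative MRI radiomics with Gaussian-kernel SVM risk scoring for
predicting tumor progression/recurrence (P/R), built as a fully
reproducible R pipeline. The intended users are imaging researchers who
want an auditable, end-to-end reference implementation of a two-modality
radiomics workflow — automatic lesion segmentation, standardized feature
extraction, kernel-SVM scoring with sequential feature selection, and
ROC/survival evaluation — that runs entirely on synthetic phantom cohorts,
so every stage is testable without access to clinical images.

## The model

Per patient, two co-registered 3D volumes are analyzed: a
contrast-enhanced T1-weighted channel (lesion hyperintense) and a
T2-weighted channel. The pipeline:

1. **Segmentation** — inside an operator seed box on CE-T1, each axial
   slice is clustered by fuzzy c-means (K = 2, fuzziness m = 2);
   memberships u_ik ∝ (1/|x_i − c_k|)^(2/(m−1)) row-normalize to 1 and
   centroids are membership²-weighted means. Voxels with bright-cluster
   membership > 0.5 are stacked, the largest 26-connected 3D component is
   kept, holes are filled, and the mask is mapped onto T2 by affine
   transform with linear interpolation.
2. **Features** — 107 features per modality, 214 per patient:
   14 shape + 18 first-order intensity ("32 first-order") and
   24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM ("75 textural"),
   computed in 3D on a 32-level fixed-bin-count discretization. Key
   definitions: GLCM cluster shade Σ_{i,j} (i + j − μ_i − μ_j)³ p(i,j),
   cluster prominence the same with exponent 4, GLSZM gray-level
   non-uniformity Σ_g (Σ_s P(g,s))² / N_z.
3. **Scoring** — features are z-scored; a soft-margin SVM with the unit
   Gaussian kernel G(x_n, x) = exp(−‖x_n − x‖²) is trained by SMO; the
   per-patient risk score is

       f(x) = Σ_{n=1}^{N} w_n y_n G(x_n, x) + b

   with support vectors x_n, dual weights w_n, labels y_n = ±1 and bias b.
   Sequential forward selection adds, at each step, the feature maximizing
   repeated stratified 10-fold cross-validation performance, stopping at
   improvement < 10⁻⁶ or 4 features. Reported scores are out-of-fold
   (cross-validated) by default.
4. **Evaluation** — AUC as normalized Mann–Whitney U, Youden-optimal
   cutoff (positive when score > cutoff), Kaplan–Meier curves with
   log-rank tests, univariate Cox proportional-hazards gating (p < 0.05)
   into a multivariate model, group tables (chi-square without continuity
   correction / Fisher / Mann–Whitney U), and ICC(2,1) agreement.

The synthetic cohort generator plants the structure this analysis assumes:
lesions whose internal texture differs between risk classes in
distributional asymmetry (third/fourth-moment features) and size-zone
granularity, clinical covariates (sex, age, resection extent, bone
invasion, ADC), and exponential-hazard time-to-P/R with uniform 14–149
month administrative censoring, calibrated to ~15% event prevalence.

## Worked example

```r
library(radscore)

ph  <- generate_phantom_pair(phantom_spec(), class_label = 1, seed = 7)
seg <- segment_volume(ph$pair, seed_box(c(5, 28), c(5, 28), c(4, 7)))
mask_dice(seg$mask, ph$mask$mask)
#> [1] 1
fv <- extract_feature_vector(ph$pair, seg)
round(fv[c("T1_glcm_ClusterShade", "T1_glszm_GrayLevelNonUniformity",
           "T2_glcm_ClusterProminence", "T2_glcm_ClusterShade")], 3)
#>            T1_glcm_ClusterShade T1_glszm_GrayLevelNonUniformity
#>                         606.958                          12.139
#>       T2_glcm_ClusterProminence            T2_glcm_ClusterShade
#>                       36661.294                         873.036
```

The four features printed are the cluster-shade / cluster-prominence /
gray-level-non-uniformity descriptors this kind of analysis tends to
select: the positive shade values reflect the right-skewed lesion texture
planted for the high-risk class.

A small end-to-end run (60 patients, truth masks, 5 CV repeats):

```r
cfg <- default_config(seed = 11)
cfg$n_patients     <- 60L
cfg$svm$n_repeats  <- 5L
cfg$use_truth_masks <- TRUE
s <- run_pipeline(cfg, out_dir = "run1")
#> events: 9 / 60
#> AUC svm 0.94 (cutoff -0.794), adc 0.75, combined 0.94; log-rank p 3.5e-07
```

`run1/` then contains `features.csv` (60 × 214), `scores.csv`,
`selected_features.json`, ROC/Cox/KM tables, `summary.json`, the frozen
`config.json` and a stage log. The cross-validated AUC of 0.94 means the
out-of-fold SVM score separates simulated progressors from
non-progressors; the log-rank p-value tests the score-dichotomized
progression-free-survival split.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "radscore.R", package = "radscore"))')
Rscript $CLI schema                                   # print default config
Rscript $CLI simulate --n-patients 128 --seed 1 --out cohort/
Rscript $CLI run-all  --seed 1 --out run1 --use-truth-masks
Rscript $CLI segment  --input cohort/ --out seg/      # per-patient Dice
```

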