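---
title: "Methods: integrated CT radiomics and transcriptomics modelling"
author: "radiogenomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated CT radiomics and transcriptomics modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
**radiogenomix**, the assumptions behind them, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

## The pipeline at a glance

The package addresses three questions about locally advanced head and
neck squamous cell carcinoma (HNSCC) treated with primary
radiochemotherapy: can CT radiomics identify the gene-expression-defined
molecular subtypes; can it act as a surrogate for published gene
signatures; and does combining a radiomics signature with
transcriptome-derived metagenes improve the prognosis of loco-regional
control (LRC)? The implementation is organised as independently usable
stages: image pre-processing and feature extraction, augmentation-based
stability filtering, consensus-cluster-guided reference-batch ComBat,
expression-side subtyping and gene-set scoring, a model-development
engine (transforms, redundancy clustering, MRMR + Borda selection under
repeated cross-validation, logistic/Cox fits), and an evaluation layer.
`runPipeline()` wires the stages together; each writes plain-file
artifacts so a run is restartable and inspectable.

## Image pre-processing and features

CT volumes are resampled to 1.0 mm isotropic voxels with tricubic
(Catmull-Rom) interpolation; masks use trilinear interpolation
thresholded at 0.5 (values exactly 0.5 count as inside). The output
grid is centre-aligned with the input extent, which also avoids
sampling exactly on voxel-face midpoints at integer spacing ratios —
at a 2:1 ratio an origin-aligned grid would put every boundary sample
exactly at 0.5 and the thresholded mask would dilate systematically.

Intensities are re-segmented, not clamped: voxels outside the closed
window [−150, 180] HU (air cavities, bone) are removed from the
*intensity* mask while the *morphological* mask keeps the full
delineation, because shape features describe the delineated geometry
while intensity, histogram and texture features describe the retained
tissue.

The Laplacian-of-Gaussian bank applies LoG filters with σ = 1…5 mm
(sampled second-derivative-of-Gaussian kernels, DC-corrected so a
constant image maps to exactly zero, radius 4σ, mirror padding,
separable passes shared across the three second-derivative terms) and
averages the five responses voxelwise into one image. Only the
statistical and intensity-histogram families are ever computed on the
LoG image — LoG morphology is meaningless (the mask is unchanged) and
LoG texture is excluded by construction rather than filtered later.

Histogram and texture features use fixed-bin-number discretisation over
the in-mask min–max range, default `nBins = 32` (config-overridable).
A constant region maps to a single grey level. Fixed bin *number* was
chosen over fixed bin *size* because the HU re-segmentation window
already bounds the range, making the discretisation robust to it.

The implemented catalogue (72 features) covers every family — 13
statistical, 2 local-intensity (1 cm³ spherical peaks), 6 morphological,
7 intensity-histogram, and 24 texture features (GLSZM with
26-connectivity, symmetric distance-1 GLCM and GLRLM each averaged over
the 13 unique 3-D directions) — and includes every feature used by the
final published models (`morph_vol_dens_aabb`, `szm_glnu`,
`log_stat_p90`, the GTV volume in cm³). Volume and the bounding-box
volume density are voxel-count based, not mesh based: the internal
oracles are voxel-based and the density of an axis-aligned cuboid is
then exactly 1. Degenerate regions propagate explicitly: a single-voxel
ROI yields NaN for undefined co-occurrence features rather than a
silent 0.

## Stability filtering

Robustness is probed with 5 in-plane rotations (−4°…+4°, about the
cranio-caudal axis, matching acquisition geometry) × 4 volume changes
(±10 %, ±20 %) = 20 variants per patient. The volume change thresholds
the signed Euclidean distance transform of the mask; because the signed
distance plateaus between ±1 voxel near the boundary, the exact target
count is reached by keeping the target number of smallest-signed-distance
voxels, i.e. EDT thresholding with a deterministic tie-break inside the
critical shell (achieved volume is exact, well within the 1 %
tolerance). Unreachable targets (masks too small to erode 20 %) drop
the variant with a warning.

Per feature, agreement across variants is the one-way random-effects
ICC(1,1) = (MSB − MSW)/(MSB + (k−1) MSW) with an F-distribution 95 % CI;
the one-way form treats augmentation variants as exchangeable raters,
which sidesteps the absolute-agreement/consistency distinction of
two-way forms. Features are retained when the CI lower bound is
≥ 0.75. Zero-variance tables are defined as ICC 1 with a degenerate CI
and flagged. The GTV volume bypasses this filter in the pipeline: the
volume augmentation perturbs it by construction, and it is a forced
clinical covariate downstream, not a candidate radiomics feature.

## Reference-batch harmonisation

Patients are embedded by PCA (components to 90 % cumulative variance)
of the z-scored statistical, intensity-histogram and texture features,
then consensus-clustered for each k in 2…6 (100 resamples of 80 % of
patients, complete-linkage hierarchical clustering inside and on
1 − consensus). "Did not change clusters across k" is made precise as
pairwise co-assignment at every k; the largest such patient set is the
reference, ties broken by first occurrence. When clustering is
ambiguous at every k (proportion of ambiguous consensus entries
> 0.35 for all k — the standard PAC diagnostic), the cohort has no
stable split and everyone is reference. ComBat adjustment (location
and scale, empirical-Bayes shrinkage, non-parametric prior by default)
then aligns the outliers to the reference batch, which is returned
bit-unchanged. Features with zero within-batch variance pass through
unadjusted with a warning. Note that empirical-Bayes ComBat is not
exactly idempotent — shrinkage deliberately leaves small residual
effects — so the package's invariant is that a second pass changes the
data by an order of magnitude less than the first removed.

## Expression-side computations

**Subtyping.** Expression and centroid profiles are restricted to their
shared genes; each sample is median-centred *over that shared set* (the
operation is then self-contained given only the centroid file; the
alternative — centring over all genes — is a caller-side change) and
Pearson-correlated with the four subtype centroids. A sample is
unclassified when max r < 0.2 or the gap between the two best is
≤ 0.2 — note the deliberate asymmetry (strict < vs ≤) in the two
boundaries, implemented exactly as stated. Constant profiles are
flagged unclassified.

**Signature classes.** Per gene z-scoring (parameters stored at fit
time), k-means with k = 2 and 10 restarts under a fixed seed, classes
relabelled so class 1 has the higher mean signature expression.
Transfer applies the frozen z-parameters and assigns by Euclidean
distance to the stored centroids, ties to the lower-indexed centroid.
Transfer of the fitting cohort reproduces the fitted labels exactly.

**Gene-set variation scores.** Per gene, a Gaussian kernel CDF
statistic with bandwidth s/4 (s = the gene's sample SD; zero-SD genes
dropped); per sample, genes are ranked by that statistic in decreasing
order (ties broken by gene order after a stable sort) and weighted
symmetrically by |rank − (p+1)/2|; a weighted random walk with
exponent τ = 1 steps up by normalised in-set weight and down by
1/(p − m); the score is the running-sum value of maximal absolute
magnitude (signed maximum deviation), which is bounded in [−1, 1].
Scores are computed per cohort separately — the function never pools
across calls, so discovery and validation stay leak-free. Sets with
fewer than two measured genes are skipped with a warning. The
implementation is validated against a brute-force oracle written as
explicit loops.

## Model development

All transforms are fitted on the discovery cohort only and transferred
frozen. The Yeo–Johnson λ is chosen by maximum likelihood over [−3, 3]
(0.25-grid, then golden-section refinement to 10⁻⁵); z-shift and
z-scale are the mean and SD of the transformed discovery values, with a
zero-SD error naming the offending feature. The published model tables
can be used directly: `fittedModel()` accepts printed coefficients and
transform parameters and `predictModel()` applies them as a pure
function.

Redundant features are clustered by complete linkage on
1 − |Spearman ρ| cut at 0.3; the representative is the feature with the
highest mean |ρ| to its co-members, ties by name order. For prognostic
signatures, features with |ρ| > 0.5 to the tumour volume are discarded
first, because the volume is forced into the model anyway.

MRMR ranks features greedily by the quotient criterion
relevance/mean-redundancy, both as mutual information with 4-bin
equal-frequency discretisation of continuous variables; survival
targets use the event indicator at a 24-month horizon (patients
censored earlier are excluded from the ranking as status-unknown).
Ties break by feature-name order, making the ranking deterministic.
Within 33 repetitions of stratified 3-fold cross-validation, each
training fold is ranked and an inner 3-fold search picks the per-fold
model size by AUC (classification) or C-index (survival) — the
interpretation chosen for the per-fold size, since the alternative (a
fixed cap) leaves the reported "median number of features" undefined.
The enhanced Borda score — not defined in the original description and
therefore fixed here as the occurrence-weighted normalised Borda sum
Σ<sub>folds selecting f</sub> (M − rank + 1)/M divided by the total
number of folds — aggregates the rankings; the final model uses the
top features at the median per-fold size (rounded half up, minimum 1,
plus forced covariates for Cox). A small deterministic ridge grid
{0, 0.01, 0.1, 1, 10} with inner CV replaces Bayesian hyperparameter
search: reproducible, desk-scale, and config-extensible.

Logistic models are one-versus-all, fitted by iteratively reweighted
least squares with the chosen ridge penalty (intercept unpenalised;
convergence 10⁻⁹, 50 iterations); perfect separation at penalty 0
falls back to the smallest nonzero grid value and is flagged. Wald
(not profile) intervals match the reporting style of the published
tables. Cox models use the partial likelihood with Efron ties and the
Breslow baseline cumulative hazard (via the survival package), with
hazard ratios and Wald CIs exposed per covariate.

## Evaluation

All bootstrap reports use 600 resamples (the number stated for cutoff
selection, adopted uniformly for every CI) with the median as point
estimate and percentile 95 % bounds. The f1 reference value is
formalised as the f1 of the always-positive classifier, 2π/(1+π) for
prevalence π — the label-independent rule that maximises expected f1 —
since the original definition lives in unavailable supplementary
material; candidate cutoffs are observed-score midpoints, eligibility
requires a median bootstrap f1 above the reference, and the chosen
cutoff maximises the CI lower bound (flagged if nothing is eligible).
Risk stratification scans observed-risk midpoints between the 10th and
90th percentiles (avoiding degenerate extreme splits) and minimises the
discovery log-rank p; apply mode only ever splits at the stored
threshold. The Hosmer–Lemeshow test uses deciles of risk with ties
kept together, merging degenerate groups, on g − 2 degrees of freedom.
The Greenwood–Nam–d'Agostino test at 24 months merges risk-decile
groups until each holds at least two events (per Demler's
recommendation; the original grouping is unstated) and compares
Kaplan–Meier observed survival (Greenwood variance) with mean predicted
survival per group on G − 1 degrees of freedom. Proportional hazards
are checked by the score-type χ² of scaled Schoenfeld residuals against
Kaplan–Meier-transformed time.

## The synthetic cohort: what it emulates, and what it does not

`generateCohort()` plants recoverable structure at the study's
conditions: a 122/84 discovery/validation split; subtype prevalences
15.6/18.5/8.3/11.2 % with the remainder generated as 50/50 centroid
mixtures (so the 0.2-gap rule has true positives to catch); expression
as centroid + N(0, 0.25) per gene plus an additive/multiplicative batch
effect on the validation centre (shift 0.8, scale 1.2 — the real
magnitudes are unpublished; these are moderate values that ComBat must
visibly remove); tumours as spherical-harmonic-perturbed spheres (the
harmonics evaluated in a randomly rotated frame so lobes are
generically misaligned with the axis-aligned bounding box) filled with
a Gaussian random field whose variance rises and correlation length
falls with the heterogeneity dial — so shape irregularity lowers
`morph_vol_dens_aabb` and texture heterogeneity raises `szm_glnu` in
expectation, the two dials the subtype model uses; air-like (−800 HU)
and bone-like (1000 HU) inclusions that exercise the re-segmentation
window; and exponential survival from a ground-truth Cox model (independent
hazards on the image-texture dial, tumour volume, and the hedgehog and
E2F pathway activations; baseline rate 0.02/month, censoring calibrated
to 30 % by bisection of a uniform censoring window). All randomness
flows from one root seed through named substreams; regeneration is
byte-identical.

What the generator does *not* emulate: CT physics (reconstruction
kernels, beam hardening, contrast), multi-lesion patients, realistic
microarray noise structure, or the true covariance of radiomics
features. Passing tests therefore demonstrate that the machinery
recovers planted structure under controlled conditions — not that the
published effect sizes would replicate on clinical data.

Two scale choices keep the default test run at desk scale: the
end-to-end pipeline tests use small cohorts (tens of patients, 14–20 mm
tumours), and the combined-vs-single-modality C-index comparison is
exercised at the feature level — the observed image feature is the
generator's planted texture dial plus measurement noise and the
metagenes come from `gsvaScores()` on the planted pathway sets — rather
than rendering and extracting thousands of image volumes. The
modelling machinery under test (Cox fitting, frozen transfer,
concordance on the held-out split) is the full package surface.

## Known limitations

* The feature catalogue is a declared subset (72 features), not the
  full IBSI set; downstream logic is feature-count-agnostic.
* Discretisation and texture-aggregation settings of the original
  analysis are unavailable; the defaults here are declared, not
  inferred.
* Non-parametric ComBat leaves small residual batch effects by design
  (see above); the reference batch itself is always exact.
* The GSVA bandwidth (s/4) and τ = 1 follow the cited method's
  defaults; only the enrichment statistic (signed maximum deviation)
  is fixed by the original description.
* Harrell's C, the log-rank test and the Cox model assume
  non-informative censoring, which the generator satisfies by
  construction but clinical data may not.
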