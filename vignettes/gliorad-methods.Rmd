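---
title: "Methods: radiomic classification of progressive vs. responsive GBM follow-up MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic classification of progressive vs. responsive GBM follow-up MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

After surgery and adjuvant therapy, glioblastoma multiforme (GBM) patients are
followed with serial multi-parametric MRI. Each follow-up time point is
eventually judged *progressive* or *responsive* under clinical response
criteria; the question this package addresses is whether that judgement can be
reproduced automatically from quantitative image features. The pipeline works
from 16 co-registered parameter maps per time point — four conventional maps
(T1, post-contrast T1 "T1pc", T2, FLAIR), five perfusion maps (CBV, CBF, MTT,
TTP, R2) and seven diffusion-kurtosis maps (FA, MD, AD, RD, MK, AK, RK) —
together with a whole-tumor mask ("Total") and a contralateral
normal-appearing white matter (NAWM) mask.

Because no patient imaging is distributed with the package, a synthetic
cohort generator reproduces the *statistical structure* of such a study and
makes every downstream stage testable end to end.

# Pipeline stages

## Delineation

The Total mask is split into a contrast-enhancing region (CER) and a
non-enhancing region (NER) by thresholding T1pc intensities at the 90th
percentile of the Total voxels. Percentiles use linear interpolation between
order statistics (`stats::quantile()` type 7); the threshold is applied
strictly, so ties fall into NER and `|CER|` never exceeds 10% of `|Total|`.
Both conventions are deliberate choices where several are defensible: the
interpolation convention is the default of the major numerical libraries, and
the strict inequality guarantees the CER size bound. A Total region with
constant T1pc would produce an empty CER; `split_total()` treats that as an
error rather than silently degrading, leaving the caller to fall back to a
Total-only analysis. Masks are voxel-index sets on a common grid; maps are
assumed co-registered, so world-coordinate handling is out of scope.

## Feature extraction

For each ROI (Total, or CER and NER) and each map, the ROI voxels are divided
by the mean of the same map over the NAWM mask, and 26 features are computed
on the normalized intensities:

* **6 histogram features** — mean, coefficient of variation (population SD /
  mean), 90th and 10th percentiles (same percentile convention as the
  delineation), skewness, and kurtosis. Moments use the population
  (n-denominator) convention and kurtosis is non-excess (a normal sample
  gives ≈ 3); both conventions are stated here because toolkits differ and
  the choice affects absolute feature values, not rankings of well-separated
  classes.
* **20 co-occurrence texture features** — the Haralick / Soh–Tsatsoulis /
  Clausi set (autocorrelation, contrast, correlation, cluster prominence,
  cluster shade, dissimilarity, energy, entropy, homogeneity, maximum
  probability, sum of squares: variance, sum average, sum variance, sum
  entropy, difference variance, difference entropy, IMC1, IMC2, IDN, IDMN)
  computed from one gray-level co-occurrence matrix (GLCM) per (map, ROI).

The GLCM is built after rescaling the ROI's normalized intensities linearly
onto integer levels 1–64 (minimum to 1, maximum to 64, rounded half-up;
a constant ROI maps to level 1). Co-occurrences are counted at distance 1
for the four in-plane directions (0°, 45°, 90°, 135°), symmetrically, slice
by axial slice, keeping only pairs with both voxels inside the ROI, and all
slices and directions are pooled into a single 64×64 matrix before
normalization. Through-plane offsets are excluded because clinical
acquisitions are anisotropic (slice spacing well above in-plane resolution),
which is also why a 2-D co-occurrence routine applied in-plane over a 3-D
ROI is the appropriate realization of "3-D texture" here. Pooling counts
before normalizing (rather than normalizing per direction and averaging
features) was the open design choice; it weights each direction by its
number of valid pairs, which is the behavior of the standard `graycomatrix`
accumulation. Entropy-type features use base-2 logarithms with
\(0 \log 0 = 0\). A GLCM with a single occupied level has zero marginal
variance; correlation, IMC1 and IMC2 are then reported as 0.

With all 16 maps this yields 416 features per ROI (26 × 16): 416 columns for
the Total delineation and 832 for CER&NER, 1248 over all three ROIs. Columns
are named `<map>_<feature>_<roi>`. Finally every feature column is min–max
scaled to [0, 1] using **all** time points — labeled and unlabeled alike.
This reproduces the original cohort-wide normalization exactly, although it
leaks marginal scale across cross-validation folds; `scale_features()` takes
a `population` argument for a fold-safe variant when the leak matters.

## Feature selection

Six rankers are run: mRMR (MID criterion), ReliefF (k = 10 neighbors),
information gain, Pearson's chi-square, and random-forest mean decrease in
accuracy / in Gini (10,000 trees by default). The information-theoretic
rankers discretize each feature into up to 10 equal-frequency bins, capped at
roughly n/5 bins so the estimates do not saturate on small training folds —
an approximation to the original toolkit's unstated discretization defaults.
The mRMR variant (difference form, MID) is likewise a documented default
among the common variants.

Inside round 1 of a leave-one-patient-out cross-validation (LOPOCV), each
ranker is fit on every fold's training set: 6 methods × 29 folds = 174
complete rankings per dataset in the reference setting. The rankings are
fused with rank products: every feature appearing in any ranking's top 10 is
a candidate, each candidate is scored by the geometric mean of its rank
positions across *all* rankings, and the 10 best scores form the dataset's
fixed feature set. The geometric mean orders candidates identically to the
raw 174-fold product while staying in floating-point range; ranks outside
the top 10 still contribute their full positions, since only the candidate
set — not the rank source — is restricted. Score ties break
lexicographically by feature name so output is deterministic.

## Classification benchmark

Round 2 of the LOPOCV trains seven classifiers on the first k fused features,
k = 1…10: LDA; linear and RBF SVM (C = 1, σ = 1); random forest (1000 trees,
per-tree balanced class subsampling); AdaBoost (1000 trees); stochastic
gradient boosting (1000 trees, learning rate 0.1, subsample 0.5); and
RUSBoost (1000 trees, learning rate 0.1, per-iteration random undersampling
of the majority class to the minority count). The boosters' base learners are
depth-limited trees — stumps for AdaBoost and RUSBoost, depth 3 for SGB —
the common defaults where tree depth is otherwise unspecified. Class
imbalance is handled only where a classifier's stated settings do so;
the performance measure itself accounts for it.

Each fold's predictions are pooled over all labeled time points before one
balanced accuracy rate (BAR = mean of sensitivity and specificity,
"progressive" positive) is computed per cell. The full benchmark covers
2 delineations × 4 modality sets × 7 classifiers × 10 feature counts =
560 cells. A master seed fans out to per-(cell, fold) streams via a string
hash, so runs are reproducible and cells are independent of evaluation
order. A degenerate fold fit (for example LDA on a zero-within-class-variance
feature) falls back to predicting the training majority class rather than
aborting the whole grid.

## Group comparison

The 560 BAR values are rank-transformed with midranks (ties get the average
of their positional ranks) and compared in four groupings: delineation ×
modality × classifier (56 groups of 10), delineation × modality (8 of 70),
delineation × classifier (14 of 40) and delineation × feature count (20 of
28). Each grouping gets a tie-corrected Kruskal-Wallis test and a Dunn-Šidák
post-hoc comparison of group mean ranks. Comparison intervals have common
half-width \(c\sqrt{\sigma^2/(2n_g)}\), where \(\sigma^2\) is the
tie-corrected rank variance and \(c\) the normal critical value at the
Šidák-adjusted level \(1-(1-\alpha)^{1/m}\) over all \(m\) pairwise
comparisons; with equal group sizes two intervals are disjoint exactly when
the mean-rank difference is significant at the adjusted level, which is the
only property the decision rule uses. The normal approximation for mean-rank
differences is standard for Dunn-type tests; exact small-sample tables are
not used. α defaults to 0.05 and is configurable. Ties for the top-ranked
group break deterministically by group name.

# The synthetic cohort

`generate_cohort()` emulates a 29-patient cohort contributing 55 complete
labeled time points (34 progressive, 21 responsive — each patient carries one
label across its labeled scans) plus unlabeled pre-decision scans
(default one per patient) that enter only the cohort-wide feature scaling.

Geometry is deliberately simple: an axis-aligned ellipsoidal tumor whose
outermost 25% of normalized radius is the "enhancing rim", and a spherical
contralateral NAWM reference region, both on a common grid (default
64 × 64 × 32 voxels). Each map is a sum of tissue baselines (background /
NAWM / tumor; arbitrary distinct constants of order 100 per map, irrelevant
downstream because of NAWM normalization) and Gaussian voxel noise (default
SD 8). Half the noise variance is i.i.d. per voxel and half lives on 4-voxel
blocks, so percentile sets form spatially coherent clusters the way real
contrast enhancement does rather than salt-and-pepper voxels. Two
multiplicative factors per (time point, map) complete the model: a global
scanner gain (log-normal, SD 0.08) that cancels under NAWM normalization,
and a tumor-local biological jitter (log-normal, SD 0.10) that does not —
this is what gives the two classes finite overlap and keeps classification
from being trivially perfect.

The class signal lives in T1pc and CBV only: every tumor's rim is mildly
enhancing (+15% over the tumor baseline), and progressive time points add
`effect_size` × baseline on top (default `effect_size = 1`; 0 removes all
class signal, and unlabeled scans of progressive patients carry half the
effect, mimicking pre-decision scans). All other maps are identical in
distribution across classes.

What the generator does **not** emulate: MR physics and k-space artifacts,
registration error, partial-volume effects, irregular tumor shapes, necrotic
cores, infiltrative non-enhancing tumor, or inter-patient anatomical
variability. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers planted signal at realistic sample sizes —
not that the classifiers would reach any particular accuracy on clinical
images.

# Numerical and testing choices

* Percentile convention everywhere: linear interpolation (type 7); rescaling
  rounds half-up; a constant sample maps to gray level 1 and a constant
  feature column scales to 0.
* Determinism: one integer seed reproduces a cohort bit-exactly, and one
  master seed reproduces the full benchmark grid; stochastic learners get
  per-(cell, fold) seeds derived by hashing.
* Tests run the pipeline at reduced problem sizes chosen once: 20 × 20 × 10
  voxel grids (the smallest at which the CER split reliably contains in-plane
  co-occurrence pairs), ensembles of 30–200 trees, and a reduced benchmark
  grid for the effect-recovery checks. The effect-recovery tests keep the
  study's cohort counts — 29 patients, 55 labeled points, 34/21 — because
  the null behavior of the pipeline depends on the ratio of sample size to
  feature count: the fixed fused feature set is selected using all labeled
  patients (the faithful reproduction of the two-round design), which is
  optimistically biased at small n. At 10 labeled points a null cohort's
  grid-mean BAR sits near 0.7 for exactly this reason; at the study's 55 it
  is ≈ 0.5.
* GLCM and all 20 texture features are verified against brute-force oracles
  (pair enumeration; direct summation) to 1e-10; Kruskal-Wallis against its
  closed form and a 2000-replicate null calibration.

# Known limitations

* The in-plane GLCM realization excludes through-plane texture by design; a
  13-direction fully 3-D variant is a possible future flag.
* WEKA-equivalent discretization for information gain and chi-square is
  approximated by equal-frequency binning.
* The cohort-wide feature scaling reproduces a known leak of marginal scale
  across folds; use `scale_features(population = ...)` for fold-safe scaling.
* The Dunn-Šidák intervals use the normal approximation and a common
  half-width construction; with unequal group sizes the disjointness rule is
  approximate (all four shipped groupings have equal sizes).
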