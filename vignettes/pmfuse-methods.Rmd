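---
title: "Methods: multimodal fusion for pathological myopia screening"
author: "pmfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fusion for pathological myopia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Pathological myopia (PM) is degenerative high myopia with structural fundus
changes — most visibly a parapapillary atrophic crescent adjacent to the
optic disc. It is rare in the population (a few percent at most), which makes
automated screening a strongly imbalanced classification problem, and its
risk factors span three very different kinds of data: what the retina looks
like (fundus photographs), inherited susceptibility (genotypes at
myopia-associated loci), and environment/demography (age, education,
occupation, and so on). `pmfuse` implements a complete screening framework
that encodes each source as a feature view, learns one classifier over all of
them, and evaluates every combination of sources under a protocol designed
for class imbalance.

## The classifier: multiple kernel learning SVM

Each modality $m$ contributes a linear basis kernel
$K_m(x_i, x_j) = \langle x_i^m, x_j^m \rangle$ over its $[0,1]$-scaled
feature view. The fused classifier uses the convex combination

$$K = \sum_{m=1}^{M} \beta_m K_m, \qquad \beta_m \ge 0,\ \sum_m \beta_m = 1,$$

inside a soft-margin SVM
$\min_{w,b,\xi} \tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$ subject to
$y_i(w^\top\phi(x_i)+b) \ge 1-\xi_i$. Labels are $+1$ for PM and $-1$ for
normal; a decision score of exactly zero is called negative (the conservative
choice for a screening score).

Two solvers are written from scratch because they *are* the core of the
package:

* **SMO dual solver** (`train_svm()`): pairwise coordinate ascent with
  maximal-violating-pair working-set selection, stopping when the largest
  KKT violation falls below $10^{-9}$. The duals satisfy
  $0 \le \alpha_i \le C$ and $\sum_i \alpha_i y_i = 0$; tests verify the
  objective against an independent interior-point QP solve and that the
  relative duality gap stays below $10^{-4}$.
* **L1-MKL weight learning** (`mkl_svm()`): alternating minimization. At
  fixed weights, the combined-kernel SVM is solved exactly; at a fixed dual,
  the weights get the closed-form group-lasso update
  $\beta_m \propto \lVert w_m \rVert$ with
  $\lVert w_m\rVert^2 = \beta_m^2\, \alpha^\top Y K_m Y \alpha$. Both
  half-steps minimize the same regularized primal, so the tracked objective
  is non-increasing; iteration stops when its relative decrease falls below
  `tol` ($10^{-5}$) or after `max_iter` (100) outer rounds. Weights start
  uniform at $1/M$ — symmetric and reproducible.

Design points that were genuinely open and how they were settled:

* The exact simplex/L1 formulation of the kernel-weight constraint is one of
  several MKL variants in use; the L1 (sparsity-inducing) form with a
  closed-form normalized-margin update was adopted and is documented here
  rather than asserted as the only possibility.
* `C = 1` is the default penalty, exposed everywhere; no tuning grid is
  built in (nested tuning is out of scope).
* Constant (zero-variance) features produce constant kernel contributions;
  the weight update naturally drives useless kernels down, so they need no
  special-casing.
* With a single view the fit degenerates to the plain kernel SVM — tested to
  be bit-identical.

## Image view: bag of visual words over SIFT descriptors

Fundus photographs are reduced to $k$-dimensional histograms of quantized
local descriptors:

1. **Preprocess** (`preprocess_fundus()`): resize to height 256 keeping the
   aspect ratio (bilinear), keep the green channel (where retinal contrast
   lives), and restrict analysis to the disc of radius
   $0.95 \cdot \min(H, W)/2$ to avoid artifacts at the field-of-view
   boundary.
2. **Detect** (`detect_keypoints()`): Harris-Laplace (corners) and
   Hessian-Laplace (blobs) over a 5-level scale pyramid with $\sigma$
   doubling from 1.6. Spatial 3×3 maxima above threshold are kept when the
   scale-normalized Laplacian peaks at their level. The detector thresholds
   (`harris_thresh = 1e-7`, `hessian_thresh = 2e-5`, Harris $k = 0.04$) are
   configuration defaults chosen so a typical rendered fundus yields
   100–1000 keypoints; the original detector settings behind the published
   pipeline are not recoverable, so these are documented package defaults,
   not reconstructions.
3. **Describe** (`describe_keypoints()`): 128-bin SIFT descriptors (4×4
   spatial cells × 8 orientation bins) from a rotated 16×16 sample grid at
   the keypoint scale, after dominant-orientation assignment from a 36-bin
   gradient histogram; L2-normalized, clipped at 0.2, renormalized, and
   quantized to integers in $[0, 255]$. Gradient-based and normalized, the
   descriptor is invariant to brightness shifts and contrast scaling, and
   stable under rotation (tested at 90°).
4. **Codebook** (`build_codebook()`): k-means (Lloyd, seeded distinct-row
   initialization) over descriptors pooled from a seeded random half of the
   training images; `k = 100` by default, keeping the image view comparable
   in dimension to the other views. The codebook is persisted as a flat text
   matrix together with its seed and the image ids used.
5. **Encode** (`encode_bow()`): nearest-centroid assignment (Euclidean, ties
   to the lowest centroid index, making encoding deterministic), occurrence
   counts, then L2 normalization (L1 available by configuration). The norm
   order is a documented package choice — L2 composes naturally with linear
   kernels. A zero-keypoint image yields a flagged all-zero vector rather
   than an error: a screening pipeline must not abort on one structureless
   image.

The per-pixel descriptor loops run in compiled code (Rcpp); everything else
is vectorized R. Within the cross-validation protocol the codebook is built
once per cohort from a seeded half of the images rather than once per fold:
k-means on descriptors is unsupervised, so no label information can leak, and
per-fold vocabularies would make the 140 fitted models incomparable.

## Genotype view: panel restriction, QC, additive encoding

The package ships a curated panel of myopia-associated SNPs (57 rs
identifiers with gene, cytogenetic location and a `linkage`/`gwas` source
tag). Genotypes (TSV of allele pairs, or VCF via `vcfR`) pass through:

* **QC** (`qc_filter()`): subjects with missing-call fraction above 5% are
  removed first; then SNPs that are monomorphic, non-autosomal, below 1%
  minor allele frequency, or failing the exact Hardy-Weinberg test at
  $\alpha = 10^{-6}$ on the remaining subjects. The thresholds are
  conventional GWAS-QC values, exposed as arguments, since the original QC
  cutoffs are not recoverable. Removal reasons partition the dropped set in
  the order just given.
* **HWE exact test** (`hwe_exact_pvalue()`): conditional on observed allele
  counts, sums the probabilities of all heterozygote counts no more probable
  than the observed one, computed by the numerically stable parity
  recurrence and verified exhaustively against full enumeration.
* **Panel restriction** (`select_panel()`): intersection with the panel in
  panel order; unmatched panel entries are reported, not fatal.
* **Encoding** (`encode_additive()`): minor-allele counts $\{0,1,2\}$ map to
  $\{0, 0.5, 1\}$; missing calls are imputed with the per-SNP mode computed
  on training subjects. Mode imputation (rather than dropping subjects)
  preserves cohort size for fusion. Inside `run_protocol()` the imputation
  is done once at cohort level — the mode of a QC'd SNP is essentially
  never altered by removing half the cohort, and per-round re-imputation
  would change the feature matrix between methods being paired; the
  per-round refit applies to the min-max scalers, where leakage would
  actually matter.

## Demographic view: cleaning, digitization, screening

`clean_table()` applies the 5% missingness rule — columns first, then rows;
columns are dropped first because subjects are the scarcer resource at 2.6%
prevalence. Remaining holes are imputed (median / mode).
`encode_and_scale()` digitizes categoricals in lexicographic level order and
min-max scales every column to $[0,1]$ with parameters fitted on training
subjects only, clipping test values. `univariate_screen()` reports a Welch
t-test per numeric column (the safer unequal-variance form of the two-sample
t-test) and a chi-square test without continuity correction per categorical
column. The screen is a report, not a filter: no selection rule is applied,
and the classifier uses every cleaned covariate.

## Evaluation protocol

`run_protocol()` implements balanced stratified cross-validation for rare
positives: per test, a stratified random half-split into A and B (class
proportions preserved, sizes within one); round 1 trains on **all**
A-positives plus an equal-count random draw of A-negatives and scores **all**
of B; round 2 swaps the halves. Ten tests give 20 result groups per method.
All seven non-empty modality subsets \{D, G, I\} are evaluated on identical
splits and negative draws (per-(test, round) RNG streams are derived from the
master seed by fixed offsets), so method comparisons are paired; the odd
subject of a class goes to half A, deterministically.

Metrics: ROC by full threshold sweep (scores ≥ threshold predict positive;
vertices from the sorted unique scores plus ±∞ sentinels), AUC by trapezoid —
identical to the tie-corrected Mann-Whitney statistic; sensitivity at a fixed
specificity setpoint (0.85 by default) by linear interpolation between the
bracketing vertices of the attainable ROC staircase; balanced accuracy as the
mean of sensitivity and specificity, the standard reading for imbalanced
screening. `compare_methods()` reports per-method AUC mean/SD over the 20
groups and pairwise paired t-tests on the matched AUCs, flagged at 0.05.

## Synthetic cohort generator

No cohort of this kind is publicly deposited, so `simulate_cohort()`
generates one with the same structure: 2,258 subjects at prevalence 58/2258,
genotypes for the 57-SNP panel plus 30 synthetic background markers (87
genotyped markers in total, of which the panel step retains the 57), 44
demographic/clinical variables, and a stylized 512×512 fundus rendering per
subject (circular field, shaded background, jittered bright optic disc,
vessel-like dark polylines, Gaussian noise; positives get a bright crescent
hugging the disc — a stylized parapapillary atrophy — carried by the green
channel).

Given the label, the three views are sampled independently:

* **Genotypes**: founder minor-allele frequencies $\sim U(0.1, 0.5)$;
  controls in Hardy-Weinberg proportions; case genotype probabilities
  reweighted per SNP by $\mathrm{OR}^{(\text{minor-allele count})}$ and
  renormalized — the standard additive-risk construction with a closed-form
  case/control frequency relationship.
* **Demographics**: latent Gaussians with additive standardized shifts in
  cases; categorical variables are quantile-binned from the shifted latent,
  so both test paths (t-test, chi-square) see real signal.
* **Images**: the crescent contrast, multiplied per case by a $U(0.7, 1)$
  severity factor.

**Default effect sizes.** The generator's defaults are the study conditions,
and the condition being emulated is the observed modality performance
profile: demographic information weakest (AUC ≈ 0.61), genotypes
intermediate (≈ 0.77), images strongest (≈ 0.85), fusion best. Because the
achieved AUC of a small-sample SVM cannot be derived analytically from raw
effect sizes, the defaults were set by running the genotype-only,
demographic-only and image-only pipelines at the documented evaluation scale
(n = 600) and choosing values that land each single-modality AUC on that
profile: odds ratio 2.8 for GWAS-sourced panel SNPs and 1.4 for the first 20
linkage-sourced SNPs (GWAS hits carry the better-established effects);
standardized demographic shifts of 0.2–0.5 on eight variables (age,
education, income, occupation, urbanicity, smoking, outdoor time); crescent
contrast 0.9 with the severity jitter above. These are fixed defaults, all
overridable in `simulation_config()`.

**What the generator does not emulate**: linkage disequilibrium between
panel SNPs, population stratification, realistic retinal texture, camera
artifacts, or correlation between modality signals within a subject. Passing
the end-to-end tests therefore demonstrates that the pipeline's mechanics
and the fusion principle work under controlled complementary signal — not
that these numbers transfer to any real cohort.

## Problem sizes used by the test suite

The heavier checks run at deliberately chosen desk scales: the fusion-trend
check simulates the default cohort scaled to n = 600 (codebook from a seeded
half of the images, ten protocol seeds of 10×2 rounds); the image
separability check uses 100 + 100 rendered images at contrast 0.8 with a
60/40 train/test split; solver cross-checks use 50 random problems of up to
30 subjects; the HWE test is verified exhaustively for all genotype tables
with at most 20 subjects. The acceptance script
(`scripts/acceptance.R`) repeats the full n = 600 pipeline end to end for a
single protocol seed.

## Numerical choices and degenerate inputs

* Kernel PSD validation tolerates eigenvalues down to
  $-10^{-8}\max(1, \max|K|)$ — roundoff scale for Gram matrices of scaled
  features.
* SMO stops at KKT violation $10^{-9}$; quadratic-step denominators are
  floored at $10^{-12}$ against division by zero for duplicate points.
* Ties: a zero decision score predicts negative; nearest-centroid ties go to
  the lowest index; a MAF of exactly 0.5 polarizes to the alphabetically
  first allele.
* Degenerate images (all-constant) flow through the whole pipeline and
  produce a zero BOW vector; single-class label vectors, empty subject
  intersections, non-PSD kernels, and all-missing SNPs raise classed errors
  (`pmfuse_error_*`) rather than generic ones.

## Known limitations

* Linear kernels only; no RBF/polynomial kernels, no $L_p$-norm MKL for
  $p \neq 1$, no probability calibration, no multi-class extension.
* The protocol's balanced training sets are small when prevalence is low;
  per-group AUCs are correspondingly noisy, which is why all reporting
  aggregates over the 20 matched groups.
* The SNP view ignores linkage disequilibrium; panel SNPs are treated as
  independent features.
* Serialized models embed their training views (needed by the dual
  expansion), so model files grow with the training-set size.
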