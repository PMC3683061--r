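# pmfuse

Multimodal fusion of retinal fundus images, SNP genotypes and
demographic/clinical covariates for pathological myopia screening.

Pathological myopia (PM) — degenerative high myopia with structural fundus
changes such as a parapapillary atrophic crescent — is a leading cause of
irreversible visual impairment, and at population prevalence of a few percent
it is a textbook imbalanced screening problem. Its risk factors live in three
very different kinds of data: retinal appearance, genetic susceptibility and
demographics/environment. `pmfuse` is for researchers who want to study
whether **fusing** these heterogeneous sources improves automated detection,
and for methodologists who want a compact, fully testable reference
implementation of the underlying machinery.

## What is inside

The core classifier is a **multiple kernel learning (MKL) SVM**: each
modality *m* contributes a linear basis kernel
K_m(x_i, x_j) = ⟨x_i^m, x_j^m⟩ over its [0,1]-scaled feature view, and the
fused classifier uses the convex combination

    K = Σ_m β_m K_m,   β_m ≥ 0,  Σ_m β_m = 1

inside a soft-margin SVM (penalty C). Both solvers are written from scratch:
an SMO dual solver (maximal-violating-pair working sets, box and equality
constraints verified against an independent QP solve) and the closed-form
L1-MKL weight update β_m ∝ ‖w_m‖, alternated with SVM re-solves under a
provably non-increasing objective. The learned weights double as a readout of
each modality's contribution.

Around it, the package implements the full pipeline:

* **Image view** — bag of visual words: green-channel extraction, resize to
  height 256, 0.95-radius field mask, Harris-Laplace + Hessian-Laplace
  keypoints over a 5-level scale pyramid, 128-bin SIFT descriptors
  (compiled hot loop), seeded k-means codebook (k = 100), L2-normalized
  occurrence histograms.
* **Genotype view** — TSV/VCF readers, QC (subject call rate, monomorphic,
  non-autosomal, MAF, exact Hardy-Weinberg test), restriction to a shipped
  panel of 57 myopia-associated SNPs from linkage and GWAS sources, additive
  {0, 0.5, 1} encoding with training-mode imputation.
* **Demographic view** — 5% missingness cleaning, categorical digitization,
  training-fitted min-max scaling, Welch-t / chi-square univariate screen.
* **Evaluation** — balanced stratified cross-validation for rare positives
  (10 tests × 2 rounds; training on all positives of one half plus an equal
  random draw of negatives; testing on the entire other half), identical
  splits across all 7 modality combinations, ROC/AUC (= tie-corrected
  Mann-Whitney), sensitivity at specificity 0.85, paired method comparison.
* **Synthetic cohort generator** — seeded, byte-reproducible cohorts
  (default n = 2258, prevalence 58/2258) with HWE-consistent genotypes under
  per-SNP allelic odds ratios, latent-shift demographics, and stylized
  fundus renderings whose positive class carries a crescent of configurable
  contrast; ground truth written to JSON.

## Worked example

Simulate a small cohort, extract all three feature views, fit the fused
model, and run the evaluation protocol:

```r
library(pmfuse)

cfg <- simulation_config(n_subjects = 200, prevalence = 0.1, seed = 5)
simulate_cohort(cfg, "demo_cohort")
bundle <- load_cohort("demo_cohort", seed = 5)
#> select_panel: matched 55/57 panel SNPs
#> match_subjects: D=197, G=200, I=200; 200 labelled; 197 matched

fit <- mkl_svm(lapply(bundle$views, function(x)
  feature_view(x, scaler = fit_minmax(x))), unname(bundle$labels), C = 1)
fit
#> Multiple kernel learning SVM (3 basis kernels)
#>   n = 197 | C = 1 | outer iterations: 25
#>   kernel weights:
#>      D      G      I
#> 0.0001 0.2118 0.7881

ev <- run_protocol(bundle, n_tests = 10, seed = 1)
ev
#> Protocol evaluation: 10 tests x 2 rounds, 7 methods, seed 1
#>  method n_groups  auc_mean     auc_sd sensitivity_at_setpoint
#>       D       20 0.5091299 0.07666336                 0.16100
#>       G       20 0.8018724 0.09523638                 0.58975
#>       I       20 0.9782010 0.01923902                 0.96500
#>     D+G       20 0.7936287 0.11060025                 0.60275
#>     D+I       20 0.9782578 0.01905678                 0.96500
#>     G+I       20 0.9817665 0.01830712                 0.98000
#>   D+G+I       20 0.9815979 0.01816133                 0.98000
```

Reading the output: two panel SNPs sit on the X chromosome and are removed
by QC (55/57 matched); three subjects lose too many covariates to the 5%
missingness rule (197 matched). The MKL weights say the image view carries
most of the discriminative signal in this small cohort, the genotype view a
meaningful share, and demographics almost none — consistent with the
per-method table below it, where the image-containing combinations dominate
(mean AUC over the 20 cross-validation groups, with the sensitivity each
method achieves at specificity 0.85). On larger, harder cohorts (lower
prevalence, weaker per-case image severity) the fused model's advantage over
the best single view becomes the interesting quantity.

A thin command-line front end over the same functions is installed at
`inst/cli/pmfuse.R` (`simulate`, `extract`, `train`, `evaluate`, `compare`).

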