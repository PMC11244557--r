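---
title: "Mapping sex-by-genotype interactions in brain connectivity and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex-by-genotype interactions in brain connectivity and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorph)
```

## The problem

Many neurodevelopmental conditions show strong sex differences in
prevalence and presentation. A standard design for dissecting them in
mouse models crosses sex with genotype (wild-type vs mutant, 2x2) and asks,
for every measured unit — a voxel's resting-state connectivity, a gene's
expression — whether the genotype effect *differs between the sexes*: the
sex-by-genotype interaction. `dimorph` implements the two analysis arms such
a study needs, end to end, together with synthetic-data generators that
plant known effects so every stage can be validated against ground truth.

The imaging arm maps voxelwise functional connectivity from BOLD time
series and tests a factorial linear model with cluster-extent familywise
error (FWER) correction by restricted permutation. The transcriptomic arm
runs a bulk RNA-seq differential-expression (DE) pipeline tailored to the
interaction contrast and classifies significant genes by the direction of
their within-sex effects (mutant-up in males and mutant-down in females,
`M+F-`, or the reverse, `M-F+`), feeding a hypergeometric odds-ratio
enrichment engine.

## Imaging: model and procedure

### Time-series conditioning

Each subject's 4D series is processed in the order trim, nuisance
regression, spatial smoothing, band-pass:

* `trim_volumes()` removes the first 50 frames (default) for signal
  equilibration.
* `regress_nuisance()` replaces each in-mask voxel by its OLS residual on
  an intercept, six rigid-body motion traces, and the mean ventricular
  signal. An intercept is always included; collinear columns are dropped
  with a warning rather than failing.
* `smooth_gaussian()` applies a separable Gaussian (default FWHM 0.6 mm,
  sigma = FWHM / (2 sqrt(2 ln 2)) per axis in voxel units). The kernel is
  renormalized over in-mask voxels, so constants are conserved and mask
  edges are not diluted toward zero — the choice matters for small rodent
  brains where a large fraction of voxels borders the mask.
* `bandpass()` is an ideal (hard) FFT filter retaining 0.01-0.1 Hz
  (defaults) and zeroing all other components including DC; filtered
  series are therefore mean-zero. A hard filter was chosen because the
  procedure being reproduced names only the window, not a filter family;
  the trade-off is ringing for components that are not exact Fourier
  frequencies, which is immaterial for the correlation statistics computed
  downstream.

Each stage is linear in the data and touches only in-mask voxels; both
properties are enforced by tests.

### Connectivity mapping

Three per-subject maps are available, all based on Pearson correlation and
the Fisher r-to-z transform (`atanh`), with |r| clipped at `1 - 1e-7` so
perfect correlations map to a finite ceiling (`z_max()`):

* `global_connectivity()` — weighted degree centrality: for each in-mask
  voxel, the mean of z-transformed correlations with every other in-mask
  voxel.
* `local_connectivity()` — the same restricted to a sphere of
  `radius_vox` voxels (default 6). The radius is specified in voxels
  because printed mm radii and voxel counts in the literature this package
  emulates are mutually inconsistent at the stated field of view; an mm
  value is accepted and converted with a warning.
* `seed_connectivity()` — Fisher z of the correlation between each voxel
  and the mean time course of a seed block (default 3x3x1 voxels).

Averaging is done on the z scale by default (`average_domain = "z"`);
z-averaging is the variance-stabilized choice and keeps the degree metric
consistent with the seed maps, but raw-r averaging is available. Voxels
with zero temporal variance are excluded from every target set and flagged
`NaN`; `voi_score()` averages a map over a volume of interest ignoring
`NaN`s.

### Voxelwise inference and cluster correction

`voxelwise_glm()` fits, per voxel, OLS on `[1, sex, genotype,
sex*genotype]` with +/-1 effect coding (F/WT = -1, M/MUT = +1). With this
coding the interaction coefficient is symmetric in the two factors, and in
a balanced design its squared t equals the two-way ANOVA interaction F
(tested to 1e-8). `factorial_anova()` (Type-II sums of squares, Tukey HSD
on request) and `roi_ttest()` (pooled-variance two-sample t) cover
region-of-interest quantification.

`cluster_fwer()` corrects cluster extents by permutation: clusters are
maximal components of `|t| > t_thresh` (default 2.1; positive and negative
tails separately; face/6-connectivity by default), and the null is the
distribution of the *maximum* cluster extent over label permutations.
Permutations respect exchangeability under the tested null: for the
interaction (and genotype) contrast, genotype labels are shuffled within
sex strata; for sex, within genotype strata. Corrected
`p = (1 + #{perm max >= extent}) / (1 + n_perm)`, so `1/(1+n_perm)` is the
estimator floor and p is monotone in extent within a run. A
label-permutation procedure was chosen over parametric cluster inference
because it is assumption-light and exact under exchangeability; the
original procedure being emulated does not name its correction machinery,
so results can only be matched in kind.

One practical caveat the calibration study surfaced: cluster-extent
inference presupposes spatially smooth fields. On unsmoothed phantom data
the null maximum extent concentrates on 2-4 voxels and the achievable test
level collapses well below nominal; with the pipeline's 0.6 mm smoothing
in place the extent distribution is rich and the familywise error rate
lands near the nominal 0.05. The calibration functions
(`null_fwer_study()`, `interaction_detection_study()`) therefore include
smoothing, and the package documents this as a requirement, not an option,
when cluster extents are the test statistic.

## Transcriptomics: model and procedure

The DE pipeline follows the standard count-based workflow:

1. `filter_genes()` — drop genes with fewer than 100 reads in 2 or more
   samples, then the lowest-variance 15% (variance on log-CPM). Ties in
   variance are broken by keeping lexicographically lower gene IDs, making
   the filter deterministic.
2. `tmm_factors()` — trimmed-mean-of-M-values scale factors (reference =
   sample with upper-quartile closest to the mean upper quartile; trims
   0.30 on M and 0.05 on A, the method's canonical defaults; factors
   rescaled to geometric mean 1), computed via `edgeR::calcNormFactors`
   and cross-checked in the tests against an independent brute-force
   implementation.
3. `logcpm()` — `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`.
4. `precision_weights()` — the mean-variance trend: gene-wise linear fit,
   lowess of sqrt-residual-SD on average log2 count, per-observation
   predicted SD at the fitted value, weight = predicted-SD^-4 (inverse
   predicted variance). Tests check the weights correlate > 0.95 with
   `limma::voom` on NB data.
5. `estimate_svs()` — surrogate variables as the top sample-side singular
   vectors of the residual matrix after removing the known design
   (sex, genotype, interaction, RIN). This is deliberately the simple
   residual-SVD reading of surrogate-variable analysis rather than the
   iterative reweighting algorithm: the artifacts being emulated behave as
   dominant principal components of the error term, and two SVs (the
   default) recover a planted balanced artifact factor with |r| > 0.9.
6. `fit_interaction()` — per-gene weighted least squares of
   `logcpm ~ genotype*sex + RIN + sv1 + sv2` with effect coding. Reported
   contrasts: the within-male and within-female mutant-vs-wildtype simple
   effects (`2*(b_g +/- b_gs)`) and the interaction coefficient, with
   two-sided p from the t distribution at the residual degrees of freedom
   and BH q over interaction p values. Empirical-Bayes variance moderation
   is *not* applied — ordinary WLS t statistics are used. At the study's
   sample sizes this forgoes some power relative to moderated statistics
   but keeps the per-gene inference self-contained.
7. `classify_interaction()` — genes at interaction q < 0.05 are labelled
   by the *signs of their simple effects* (`M-F+`: mutant-down in males,
   mutant-up in females; `M+F-`: the reverse). The class names describe
   within-sex directions, so simple-effect signs — not the interaction
   sign — define membership; significant genes whose simple effects share
   a sign are reported as `concordant` rather than forced into a class.

### Enrichment

`hypergeom_enrich()` tests the overlap `a` of a query class with a gene
list inside a background universe (the post-filter gene set — an input,
never a constant): one-sided upper tail `P[X >= a]`,
`X ~ Hypergeom(N, K, n)`, with the odds ratio from the 2x2 table.
Depletion shows up as OR < 1 without a second test. When any cell is zero
the Haldane-Anscombe +0.5 correction is applied to all four cells
(flag-switchable, since conventions differ). `enrich_classes()` runs a
query-by-list family and applies BH across the whole invocation — the FDR
family is everything tested together. `chromosome_enrich()` reuses the
same test per chromosome and additionally reports the percentage of each
chromosome's genes in the class. `map_homologs()` translates mouse IDs to
human symbols through a user-supplied two-column table (no network
access), dropping unmapped genes with a logged count and deduplicating
many-to-one collisions. Tests pin the hypergeometric tail to exact
enumeration for every configuration up to N = 30.

## The synthetic-data generators

`simulate_bold()` emulates: multi-subject 4D series with AR(1) Gaussian
noise (the minimal temporally autocorrelated model — no scanner physics or
physiological spectra), spatially coherent networks as voxel sets sharing
a latent AR(1) signal, and a linear mixture of six motion traces plus a
ventricular trace so that nuisance regression demonstrably removes
spurious connectivity. Planted effects are specified *on the Fisher-z
scale* per design cell (`z_cell = base_z + d_sex I(M) + d_genotype I(MUT)
+ d_interaction I(M & MUT)`), and the latent loading realizing a target z
is `w = noise_sd * sqrt(r/(1-r))`, `r = tanh(z_cell)`. Defaults follow the
emulated study: n = 10 per cell, TR 1 s, 1920 frames, 0.23 x 0.23 x 0.6 mm
voxels — on a 16x16x8 phantom grid, the package's desk-scale geometry.
The interaction is planted by default as an effect in mutant males only,
mirroring the opposite-signed within-sex phenomenology the classifier
targets.

`simulate_counts()` draws NB counts (variance mu + phi mu^2; gene-wise phi
log-normal) with baseline log2-CPM normal across genes, library sizes
uniform in 1e7-5e7, a RIN-like covariate with small gene-wise slopes, and
a binary artifact factor loading on a fraction of genes; with
`artifact_samples = "balanced"` the affected samples are split evenly
within design cells so the factor is near-orthogonal to the design — the
regime in which surrogate variables can and should recover it. Planted
fold-change sets are placed only in expressed genes (>= 1 CPM, the
field's customary floor), optionally pinned to a chromosome, and the
default cohort is the emulated study's 4/4/5/5 design. Both generators are
bit-reproducible given the spec and seed, and label every voxel/gene with
its ground-truth class.

What the generators do *not* emulate — registration errors, spatially
varying smoothness, physiological noise, UMI/duplication artifacts,
correlated gene-gene structure beyond the artifact factor — bounds what
passing tests show: the machinery is correct and calibrated under the
stated models, which is a necessary, not sufficient, condition for
well-behaved inference on real data.

## Study conditions and numerical choices

The packaged calibration studies use problem sizes chosen to make
Monte-Carlo properties measurable in minutes on one core: the imaging
studies run the 16x16x8 phantom at 120 frames with n = 5 per cell
(100 null cohorts / 50 planted cohorts, 500 permutations); the DE studies
use 2000 genes at n = 5 per cell over 50 runs. The imaging calibration
maps are seed maps computed after nuisance regression and smoothing;
trimming and band-pass are exercised by their own spectral and contract
tests instead, since the phantom has no equilibration transient and the
broadband AR(1) signal would lose most of its power (and the study most of
its runtime budget) to a 0.01-0.1 Hz cut at 120 frames.

Numerical policies, in one place: correlation clipping at `|r| <= 1-1e-7`;
t statistics at zero residual variance reported as sign(beta) * 1e6;
ANOVA effects with zero sum-of-squares under zero residual variance
reported as F = 0, p = 1; lowess-predicted residual SDs floored at 1e-4
before inversion; volumes stored as float32, computed as float64;
permutation and simulation streams fully determined by explicit seeds
(the global RNG state of the caller is saved and restored).

## Known limitations

* No despiking, motion realignment, or template registration: the imaging
  pipeline assumes registered input.
* Permutation cluster correction only; no parametric random-field theory,
  TFCE, or mixed-effects longitudinal models.
* No moderated (empirical-Bayes) variance estimation in the DE fit, and a
  non-iterative surrogate-variable estimator; both are conservative,
  simpler readings of the standard tools.
* One null-calibration clause is intrinsically knife-edged: with ~2000
  null genes, the probability of *zero* BH rejections per run is itself
  about 0.95, so a "95% of runs are clean" requirement oscillates around
  its threshold by Monte-Carlo noise alone; the uniformity of the
  interaction p values is the stabler diagnostic and is tested alongside.
* Enrichment requires user-supplied gene lists and homolog tables; the
  package performs no retrieval.
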