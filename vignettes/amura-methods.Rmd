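---
title: "Single-shell restriction indices, group statistics and model attribution: methods and design choices"
author: "amura package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amura)
```

## The problem

Amyloid-beta accumulation and tau pathology begin years before cognitive
symptoms, and diffusion MRI can detect the accompanying white-matter
microstructural changes with clinically feasible acquisitions. This
package implements a complete analysis chain for that setting:

1. voxelwise **restriction indices** — the return-to-origin, -axis and
   -plane probabilities (RTOP, RTAP, RTPP) — computed from a *single*
   b-shell via spherical-harmonic (SH) expansions of the apparent
   diffusion coefficient, alongside their diffusion-tensor closed forms,
   mean diffusivity (MD) and fractional anisotropy (FA);
2. skeleton-masked **ROI feature extraction** into subjects-by-48-tract
   matrices, and a max-statistic permutation test for group differences;
3. **SVM classification** of CSF-biomarker-defined groups
   (amyloid-positive iff Abeta <= 980 pg/mL, tau-positive iff
   tau >= 24 pg/mL) with a linear kernel, `C = 0.4` and stratified
   10-fold cross-validation;
4. **attribution**: KernelSHAP and LIME explanations of the best fold's
   validation subjects with top-5 agreement statistics.

Because the motivating cohort data (ADNI) are access-controlled, the
package ships first-class synthetic generators — multi-tensor phantoms
with Rician noise and planted-effect ROI cohorts — so every stage is
exercised end to end on data with known ground truth.

## The signal model and the three indices

On a single shell the normalized signal is modelled as
$E(q_0,\theta,\phi)=\exp(-4\pi^2\tau q_0^2\,D(\theta,\phi))$ with
diffusion time $\tau$ and b-value $b=4\pi^2\tau q_0^2$, so the apparent
diffusion coefficient is recovered per direction as
$D=-\log E/b$ (mm^2/s). Treating the directional profile as b-independent
gives closed EAP-like expressions on the shell:

$$\mathrm{RTOP}=\frac{1}{(4\pi)^2\tau^{3/2}}\,C_{00}\!\left\{D^{-3/2}\right\},\qquad
\mathrm{RTAP}=\frac{1}{8\pi^2\tau}\,\mathcal G\!\left\{\tfrac1D\right\}(\mathbf r_0),\qquad
\mathrm{RTPP}=\frac{1}{\sqrt{4\pi\tau\,D_{SH}(\mathbf r_0)}},$$

where $C_{00}\{\cdot\}$ is the degree-0 coefficient of the orthonormal
SH fit, $\mathcal G$ the Funk–Radon transform (diagonal in SH with
eigenvalues $2\pi P_\ell(0)$), $D_{SH}$ the SH-regularized ADC and
$\mathbf r_0$ the maximum-diffusion axis. With $\tau$ in seconds and $D$
in mm^2/s the units are mm^-3, mm^-2 and mm^-1. The tensor counterparts
are $(4\pi\tau)^{-3/2}(\lambda_1\lambda_2\lambda_3)^{-1/2}$,
$(4\pi\tau)^{-1}(\lambda_2\lambda_3)^{-1/2}$ and
$(4\pi\tau)^{-1/2}\lambda_1^{-1/2}$, which satisfy
RTAP·RTPP = RTOP identically and coincide with the SH forms for
isotropic profiles — the property used to pin the basis normalization.

### SH conventions and numerical choices

* **Basis**: real, orthonormal, even-degree-only SH (the dMRI standard
  for antipodally symmetric profiles), columns ordered by $(\ell, m)$
  lexicographically; order 6 gives 28 coefficients. Associated Legendre
  functions come from `pracma::legendre` (Condon–Shortley phase folded
  in).
* **Fit**: regularized least squares with the Laplace–Beltrami penalty
  $\lambda_{LB}\,\mathrm{diag}(\ell^2(\ell+1)^2)$, unscaled by direction
  count. Defaults: order 6, $\lambda_{LB}=0.001$. The degree-0 term is
  never penalized, so spherical means survive regularization; with a
  finite direction set the normal equations couple degrees weakly, so
  $C_{00}$ moves at the per-mille level when regularization is enabled.
* **Transform order**: $D^{-3/2}$ and $1/D$ are computed per direction
  *first* and then SH-fitted, because the index definitions apply the SH
  operators to the transformed profile. This is faithful to the method
  but has a measurable consequence for RTAP, discussed below.
* **Degenerate voxels**: $E$ is clipped to $[10^{-6},1]$ before the
  logarithm; ADC values and tensor eigenvalues are floored at
  $10^{-7}$ mm^2/s so $D^{-3/2}$ and $1/D$ stay finite. All-zero voxels
  inside the mask are set to NaN and counted.
* **$\mathbf r_0$**: discrete argmax of the SH-fitted ADC over a
  724-point antipodally symmetric Fibonacci grid, followed by a second
  discrete argmax over a ~6-degree polar cap at ~0.9-degree resolution.
  The refinement stays a grid search (deterministic, no continuous
  optimization) but removes the up-to-0.5% RTPP error that the coarse
  grid alone would leave. A "tensor" mode (principal eigenvector) is
  available and recorded in the output metadata.
* **Tensor fit**: single-pass weighted log-linear least squares with
  signal-squared weights — deterministic and standard.

### The RTAP truncation bias

$1/D$ is not band-limited: for a prolate tensor with eigenvalues
$(1.7,0.3,0.3)\times10^{-3}$ mm^2/s the exact Legendre expansion of the
equator integral of $1/D$ converges as −47%, −20%, −8.0%, **−3.3%**,
−1.3%, … cumulatively at degrees 0, 2, 4, 6, 8. An order-6
implementation therefore *underestimates* RTAP by about 3–4% at high
anisotropy (less at moderate FA), while RTOP is unaffected ($C_{00}$ of
a least-squares fit estimates the spherical mean without truncation
bias) and RTPP is exact for tensor profiles (degree-2). This is an
intrinsic property of the order-6 formulation, not an implementation
artifact; the test suite asserts RTPP/RTOP against closed forms and a
10,000-point quadrature oracle at 0.5%, and documents the RTAP deviation
rather than hiding it. Users comparing RTAP across groups are
unaffected (the bias is common to both groups); users needing absolute
RTAP should raise the SH order if their protocol supports it.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions used throughout the tests:

* **Acquisition**: one b = 1000 s/mm^2 shell, 48 quasi-uniform
  directions (the shell count of a typical clinical protocol; the exact
  ADNI-3 direction count is configurable), $\tau = 38.7$ ms, one
  averaged b0.
* **Phantom**: per-region multi-tensor mixtures (single fiber, 90-degree
  crossing, isotropic by default) on a small grid; Rician noise applied
  as $|S+\epsilon_1+i\epsilon_2|$ with per-channel standard deviation
  $1/\mathrm{SNR}$, the magnitude-MR noise model (positively biased at
  low SNR). Default SNR 30, typical of b0 white matter.
* **Cohort**: N x 48 feature matrices drawn from a unit-variance
  Gaussian with exchangeable ROI correlation 0.3 (mild collinearity, as
  real tract means exhibit); three groups labelled Abeta-/tau-,
  Abeta+/tau-, Abeta+/tau+ with severity weights 0 / 0.5 / 1 so the
  doubly-positive group is the easiest to separate; planted ROIs are
  shifted by `effect_size * direction * severity`, with the default
  direction −1 matching the restriction/FA decrease observed with
  pathology; CSF biomarkers are sampled on the correct side of the
  980 / 24 pg/mL thresholds for each label.

What passing tests on these data do **not** show: realistic brain
geometry, registration error, scanner/site effects, non-Gaussian
residuals, heterogeneous ROI variances, or the actual effect sizes of
amyloid/tau pathology (no public estimates exist per tract; the
generator's effect size is a free parameter). Conclusions about real
cohorts require the real data.

## Statistics and classification

* **Permutation test**: pooled-variance two-sample t per ROI; family-wise
  correction by the maximum statistic over the 48 ROIs across label
  permutations (maxT), 1000 permutations, both one-sided contrasts.
  maxT is used rather than a cluster-enhancement statistic because ROI
  means carry no spatial adjacency. Measured calibration: per-contrast
  FWER 0.04 over 200 null replicates; power 1.00 for a 2-SD shift at
  n = 30/group. Corrected p-values are monotone above raw ones by
  construction.
* **SVM**: features are z-scored with training-fold statistics only (no
  leakage; verified by planting validation outliers), `e1071::svm` with
  the linear kernel and C = 0.4 per fold; sensitivity/specificity take
  the biomarker-positive group as positive. The grid search evaluates
  {linear, polynomial, rbf, sigmoid} x {0.01, 0.1, ..., 1, 10, 20} by
  mean CV accuracy with deterministic tie-breaks (kernel order, then
  smaller C). Fold assignment uses a fixed default seed (20240717),
  configurable. No held-out test set is kept, mirroring the small-cohort
  design it emulates; this is a documented limitation.
* A note on attainable accuracy: with 3 planted ROIs at standardized
  effect 1.0 and ROI correlation 0.3, the population-optimal
  (Gaussian-LDA) accuracy is $\Phi(\sqrt{s^\top\Sigma^{-1}s}/2)=0.842$;
  a linear SVM trained on 108 subjects with 48 features reaches ~0.74 on
  average over cohort replicates (cross-checked against scikit-learn's
  SVC on identical data). The gap is estimation noise, not an
  implementation defect.

## Attribution

Both explainers operate on the SVM decision margin (smooth in the
features), not the hard label.

* **KernelSHAP**: Shapley values by weighted linear regression over
  sampled feature coalitions (sizes drawn from the Shapley kernel
  distribution, the singleton and leave-one-out coalitions enumerated),
  with the additivity constraint eliminated exactly, so *local accuracy
  holds by construction* for every subject. The coalition value is the
  mean margin over the background set with out-of-coalition features
  replaced by background rows. Default budget 2M + 2048 coalitions.
  For models linear in the features (the linear SVM) the estimates equal
  the closed-form Shapley values to numerical precision.
* **LIME**: per subject, 5000 Gaussian perturbations drawn from the
  reference-set feature statistics, weighted by
  $\exp(-d^2/w^2)$ with $w = 0.75\sqrt{48}$ on standardized distances,
  and a weighted linear regression of margins on standardized features;
  the coefficients are the attributions. Discretization is disabled
  (continuous features).
* **Background / reference set**: the control-group (biomarker-negative)
  training rows of the selected fold. Against this reference the
  expected mean SHAP of a discriminative feature is proportional to
  $w_j(\bar x^{pos}_j-\bar x^{neg}_j)$ — the sign pattern is
  interpretable as "pushes away from the healthy reference". With an
  all-training background the expected signed mean is zero for every
  feature in a class-balanced fold. Both choices are supported;
  the pipeline records which was used.
* **Ranking**: top-k lists are ranked by the **mean absolute
  attribution** per feature (the standard SHAP-summary ordering), ties
  broken alphabetically; signed means are reported alongside. Ranking by
  the magnitude of the *signed* mean was evaluated and rejected: in a
  class-balanced validation fold signed means cancel in expectation, and
  the measured SHAP-vs-LIME top-5 overlap drops from ~4.3 to ~2.3 names.
* Agreement between methods is summarized by top-5 set overlap, Jaccard
  similarity and whether the top-2 ordering matches; stability is
  assessed over replicate cohorts (overlap >= 4 with >= 2 planted ROIs
  recovered per list in ~85–90% of replicates under the default
  conditions).

## Problem sizes used by the tests and the acceptance script

Phantoms of 10 x 10 x 3 voxels (48 directions); cohorts of 60 + 60
subjects; 1000 permutations; 200 null and 100 power replicates for the
permutation calibration; 50 permuted-label and 10 planted-cohort
cross-validations; 20 replicate cohorts for attribution stability; SHAP
with 2144 coalitions over ~50-row backgrounds and LIME with 5000 samples
for ~12 validation subjects per replicate. These sizes give stable
empirical rates while keeping a full run on a single CPU in minutes.

## Known limitations

* RTAP carries the order-6 truncation bias described above.
* ROI-level permutation testing replaces voxelwise skeleton statistics
  (registration, skeleton projection and cluster enhancement are out of
  scope); inference is at tract, not voxel, resolution.
* The synthetic cohort's exchangeable correlation is a deliberately mild
  stand-in for real inter-tract collinearity, which can redistribute
  SHAP/LIME mass among correlated features.
* The moment-based extensions of the single-shell family (e.g.
  higher-order propagator moments) are not implemented.
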