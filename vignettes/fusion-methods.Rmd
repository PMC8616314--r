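---
title: "Class-structured fusion of multi-sequence radiomics features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-structured fusion of multi-sequence radiomics features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radfusion)
```

## The problem

Glioblastoma multiforme (GBM) and solitary brain metastasis (SBM) often
share the same conventional-MRI appearance: a necrotic core, an enhancing
rim, and surrounding edema. Radiomics turns delineated tumor volumes into
quantitative feature panels, but two modeling choices are usually made ad
hoc: which MRI sequence to extract from, and which classifier to trust.
`radfusion` treats both as fusion problems — features observed on several
sequences are combined into one discriminative value per feature, and
several cross-validated models are combined into one weighted consensus.

## Level 1: between-class scatter whitening

For one feature measured on $p$ sequences over $n$ training samples, the
values form $X \in \mathbb{R}^{p \times n}$. With binary class labels the
between-class scatter is

$$S = \sum_{i=1}^{c} n_i(\bar{x}_i - \bar{x})(\bar{x}_i - \bar{x})^\top,
\qquad c = 2,$$

with $\bar{x}_i$ the class mean and $\bar{x}$ the grand mean of the
columns. "Unitizing" $S$ is implemented as eigen-whitening: with
$S = Q\Lambda Q^\top$ and the retained eigenpairs $(Q_r, \Lambda_r)$,

$$W = Q_r \Lambda_r^{-1/2}, \qquad W^\top S W = I_r .$$

This is the discriminant-correlation-analysis construction, and it is the
reading under which $W^\top X$ is a $1 \times n$ row for two classes: with
$c = 2$, $S$ is rank one ($\bar{x}_1 - \bar{x}$ and $\bar{x}_2 - \bar{x}$
are anti-parallel), so exactly one eigenpair survives and each feature
compresses to one fused value per sample. The retained eigenvector is
parallel to the class-mean difference in sequence space, which the test
suite asserts to $|\cos| \ge 1 - 10^{-8}$, and the fused row has a closed
form $\lambda^{-1/2} q^\top x$ that serves as an eigensolver-independent
oracle.

```{r worked}
x <- rbind(c(1, 1, 3, 3), c(0, 2, 2, 4))
sc <- between_class_scatter(x, c(0, 0, 1, 1))
sc$S
u <- unitize_scatter(sc)
drop(crossprod(u$W, x))
```

### Numerical choices

* **Eigenvalue retention**: an eigenpair is kept when
  $\lambda > \mathrm{tol} \cdot \lambda_{\max}$ with
  $\mathrm{tol} = 10^{-10}$. No explicit $r = c - 1$ cap is needed (the
  rank enforces it); the implementation takes the leading retained column
  defensively.
* **Degenerate features** (identical class means, hence $S = 0$): the
  transform falls back to the uniform average $W = p^{-1/2}\mathbf{1}$ and
  flags the feature, so the fused matrix stays rectangular and registry
  alignment is preserved. Dropping columns silently would desynchronize
  fused tables fitted on different cohorts.
* **Sign convention**: eigenvectors are defined up to sign, so $W$ is
  flipped to make the positive-class fused mean the larger one. Outputs are
  then deterministic across eigensolvers and platforms.
* **Standardization**: features are z-scored per (sequence, feature) with
  training statistics before fusion. Scatter fusion is scale sensitive
  across sequences — without it a sequence with large raw feature scales
  dominates $S$ regardless of its class information. Whether the original
  workflow standardized features (beyond image-level normalization) is not
  stated; we standardize by design and store the statistics inside the
  fusion transform, so held-out cohorts are transformed with zero
  refitting. Zero-variance features keep scale 1 and are flagged rather
  than dropped.

## Level 2: cross-validated screening and weighted consensus

The fused table feeds a grid of five feature-selection methods (ANOVA
F-score, binned mutual information, ReliefF, L1-regularized logistic path
ranking, mRMR) crossed with three classifiers (logistic regression, RBF
SVM, random forest) — fifteen models. The identity of the original five
selectors and three classifiers is not specified in the text available to
us; these defaults are a documented substitution of standard members of
each family, registered by id and swappable through the configuration.

Each model is scored by stratified 5-fold cross-validation with the
selector refit inside every fold (the no-leakage reading; the alternative
of selecting once on the full cohort optimistically biases fold AUCs).
Models are ranked by mean CV AUC (ties: mean accuracy, then spec id), the
top 3 are refit on the full training cohort, and their predictions are
fused as

$$\hat{s}(x) = \sum_{i=1}^{3} w_i\, c_i(x), \qquad
w_i = \frac{\mathrm{acc}_i}{\sum_k \mathrm{acc}_k},$$

with $\mathrm{acc}_i$ the mean CV accuracy. $c_i(x)$ is read as the
member's class-1 *probability* (soft voting): a weighted sum of hard labels
would collapse onto weighted majority voting and waste the resolution the
accuracy weights provide. The plurality-vote baseline is kept alongside for
comparison, with ties broken toward the positive class under a warning.
The consensus score is convex in the member scores and the decision
threshold is 0.5 with class 1 on the boundary.

Tunable parameters that matter: `selector_k` (features kept per selector;
default 10 — about 10% of the default panel, a common radiomics rule of
thumb), `folds` (5), `top_k` (3), the fusion `tol` ($10^{-10}$), and the
classifier hyperparameters (RBF cost 1 and gamma $1/k$; 300 trees). All
randomness flows from one seed expanded by a namespaced derivation
(`derive_seed`), so fold shuffles, simulations, and forests are jointly
reproducible.

## VOI utilities

Delineations by two raters are accepted when their Dice coefficient
exceeds 0.9 *strictly* — boundary equality routes to review, matching the
rule's wording — and the consensus VOI is the voxelwise intersection. The
seven VOI types are the three base volumes (nET, ET, pTE), their three
pairwise morphological unions, and the triple union. Two empty masks get
Dice 1 (two empty delineations agree) with a warning; masks on different
grids are an error, never an implicit resample.

## The synthetic generator

Real cohorts of this kind are not publicly deposited, so every stage is
exercised on synthetic tables. The generative model is deliberately plain:
for sample $i$ with class $y_i \in \{0,1\}$, feature $j$, sequence $k$,

$$v_{ijk} = \delta_{kj}\, y_i + \varepsilon_{ijk}, \qquad
\varepsilon_{ij\cdot} \sim \mathcal{N}(0, \Sigma_\rho),$$

with unit variances and equicorrelation $\rho$ across sequences. A single
feature with effect $\delta$ then has closed-form AUC $\Phi(\delta/\sqrt2)$,
giving the calibration oracle, and the fused feature's population effect is
computable from $\delta$ and $\rho$, giving the complementarity and
redundancy checks: with a shared informative feature and nearly independent
noise, whitened fusion raises the effective effect (complementary
information); with $\rho \to 1$ it cannot (redundant information), and the
tests assert a mean gain of at most 0.01 there.

The **default study scenario** fixes the conditions the package is
demonstrated under: 121 training samples (61 positive / 60 negative), an
independent test cohort of 62 (33 / 29), four sequences named T1WI,
CE_T1WI, T2WI, T2_FLAIR, and the 109-feature registry panel. Two sequences
carry the bulk of the signal on *disjoint* informative blocks (12 features
each at $\delta = 1$, a moderate, realistic radiomics effect), the other
two echo those blocks weakly ($\delta = 0.3$), and $\rho = 0.2$. The
disjoint design makes the two strong sequences complementary at table
level: each singleton table discriminates on its own block only, while the
fused pair covers both, which is what the fusion-gain comparison measures
(mean single-feature AUC over the union of informative blocks, fused pair
vs. the better singleton). The per-feature complementarity property — the
fused feature beating each contributing sequence — is exercised separately
under the shared-block, low-$\rho$ configuration, where it is the
population-level prediction of the model.

What the generator does *not* emulate: realistic radiomics feature
covariance (features within a panel are strongly inter-correlated in real
data), heavy-tailed or skewed feature marginals, site and scanner effects,
and label noise. Passing tests therefore demonstrate the correctness and
calibration of the machinery, not clinical performance; the original
cohort's results are not reproducible without its data.

## Problem sizes used in the checks

The property checks run at sizes where their statistical tolerances are
meaningful: 1,000 random fixtures for the whitening/oracle identities
(deterministic, tolerance $10^{-8}$), $n = 5000$/class for the closed-form
AUC calibration (tolerance 0.02), 50 replicates of the default scenario
for the fusion gain, and 20 replicates at $n = 500$ with permuted labels
for the null calibration of the full grid (grand-mean AUC within
$0.5 \pm 0.05$). The fifteen-model grid caches per-fold feature selections
across classifiers sharing a selector, which keeps a full-grid CV run on
$n = 500$ around six seconds.

## Known limitations

* Binary outcomes only; the scatter construction generalizes to $c > 2$
  (then $r \le c - 1$ fused rows per feature) but the pipeline assumes one
  fused value per feature.
* The reader-comparison harness pairs model and reader metrics over
  class-stratified bootstrap replicates of the test set before the paired
  Wilcoxon test; how the original comparison was paired on a single test
  set is not stated, so this is a documented substitution.
* Feature extraction itself is out of scope: the package ingests CSV
  tables validated against the 109-feature registry and delegates
  extraction to external tooling.
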