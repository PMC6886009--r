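---
title: "Two-level MLM brain signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level MLM brain signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task fMRI acquired while patients rate themselves on depression-specific
(DS), paranoia-specific (PS) and diagnostically neutral (DN) statements
yields, per subject, a scans-by-voxels matrix `Y` and a design matrix `X`
with one regressor per condition plus nuisance terms. The question this
package addresses is whether condition-locked multivoxel activity patterns
carry enough structure to separate two diagnostic groups — schizophrenia
and recurrent depression — without ever thresholding a statistical map.

## The two-level multivariate linear model

**Individual level.** For each subject, the nuisance part of the design
(six rigid-body motion parameters, optional cosine drift, intercept) is
partialled out of both the data and the condition regressors
(Frisch–Waugh), leaving adjusted condition regressors `Xc` and adjusted
data. The whitened cross-covariance

    Z = (Xc' S Xc)^(-1/2) Xc' Y

with `S` the temporal covariance (AR(1) with a pooled coefficient estimated
from the GLM residuals, or the identity) is decomposed by SVD,
`Z = U L V'`. The three columns of `U` are condition-space directions
("clinical loadings"), `L` holds the component strengths, and the rows of
`V` are unit-norm voxel patterns ("eigenimages"). Because the whitener
normalizes the design half of the cross-covariance, `Z`'s singular
structure is comparable across subjects.

**Alignment.** SVD signs are arbitrary, so components are sign-aligned to a
reference subject (the first, by default) through the clinical-loading
columns, flipping `U` columns and `V` rows jointly so each subject's
reconstruction is untouched.

**Group level.** For each component rank k, the subjects' rank-k
eigenimages are stacked (weighted by their eigenvalues — see below), age
and sex are regressed out of both the stack and a ±1 diagnosis contrast,
and the group MLM `Z_G = (X_G' X_G)^(-1/2) X_G' Y_G` (subject covariance
taken as the identity, subjects being exchangeable) is decomposed by SVD.
The leading spatial singular vector is the group *brain signature*;
projecting each subject's adjusted stacked image onto it gives scalar
*subject loadings*; the hat matrix of the reduced design gives their
design-space projection. A voxelwise correlation t map
(`T = r sqrt((s-2)/(1-r^2))`, df = s − 2) visualizes each signature; with
30 subjects the one-sided p = 0.05 critical value is 1.70.

**Classification.** Diagnosis is predicted from each rank's subject
loadings by a pooled-covariance linear discriminant, evaluated with
stratified 2-fold cross-validation repeated 100 times; each repeat
contributes one pooled accuracy, and the distribution is summarized by its
median and quartiles, with ROC/AUC computed from out-of-fold discriminant
scores (schizophrenia is the positive class).

## Why the signature is re-estimated inside each training fold

Projecting all subjects onto a signature estimated from the full sample is
circular: when voxels far outnumber subjects, the estimated signature
partially memorizes each subject's idiosyncratic noise, and the resulting
in-sample loadings separate *any* labelling almost perfectly. The package
therefore re-estimates the group signature from the training subjects of
every fold and projects held-out subjects onto it, so a held-out subject
never influences their own feature. The full-sample loadings are still
computed and reported — they are the descriptive, figure-style output — but
accuracies come from the fold-internal estimates. Confound residualization
is kept as a global deterministic preprocessing step.

```{r pipeline}
library(mlmfmri)
cohort <- simulate_cohort(cohort_config(seed = 11))
res <- analyze_cohort(cohort, seed = 5)
res
```

## The synthetic cohort generator

The generator emulates the study conditions: 16 schizophrenia and 14
depression subjects; a block paradigm of four 32 s active blocks per
condition (four 8 s statements each), each followed by 20 s rest, cycling
DS→DN→PS, with 40 s lead-in and lead-out rest for a 704 s run — 352 scans
at TR = 2 s; AR(1) noise (rho = 0.3) with a 128 s cosine drift; ages drawn
from group normals (36.4 and 45.3 ± 12.5 years) truncated to 18–65; sex
counts exactly 10M/6F and 5M/9F. Motion files are smooth low-amplitude
random walks used only as nuisance regressors.

**Fixed-point component planting.** Writing the signal as
`Y = Xc B + drift + noise` with `B` built from per-condition maps and
group-shifted amplitudes does *not* confine a planted group effect to one
component: block-design condition regressors are correlated, so an
amplitude shift on one condition rotates *all* singular vectors of `Z`. The
generator therefore plants components directly as singular components of
the quantity the method estimates: with `T = (Xc' S Xc)^(-1/2) (Xc' Xc)`
and its SVD `T = P S_T Q'`, subject i's coefficient matrix is

    B_i = Q diag(a_i / s_T) M,

where the rows of `M` are three orthonormal spatial maps (seeded Gaussian
blobs confined to disjoint slabs) and `a_i` the subject's component
amplitudes. Then `Z_i = P diag(a_i) M` exactly: amplitudes are eigenvalues,
`Q`-directions are clinical loadings, maps are eigenimages, and a group
shift on amplitude k lives in component k alone.

Two practical subtleties. First, condition symmetry of the block design
makes the two leading singular values of `T` nearly degenerate, so each
subject's motion regressors would otherwise rotate the planted rank-1/2
directions arbitrarily within that plane; every subject's `(P, Q)` basis is
Procrustes-aligned to the motion-free reference geometry (a joint rotation,
preserving `T` up to the degeneracy gap). Second, SVD signs are fixed with
the same largest-entry-positive convention the analysis uses, so planted
signs are consistent across subjects.

**Consequence for stacking.** With exact confinement the group amplitude
difference lives in the eigenvalues, not in the unit-norm eigenimages, so
the pipeline stacks eigenvalue-weighted eigenimages
(`stack_eigenimages(..., weighting = "eigenvalue")`); unweighted stacking
remains available and is the function's default for inspecting raw
patterns.

**Amplitude calibration.** Defaults are component amplitudes (150, 100,
50), subject jitter SD 10, and a +30 schizophrenia-minus-depression shift
on rank 3. In per-voxel terms these correspond to peak GLM effects of
roughly 0.5–2 noise standard deviations — ordinary block-design effect
sizes — and keep planted eigenvalues above the random-matrix noise floor of
`Z` (noise_sd × sqrt(voxels) ≈ 45 on the default 16×16×8 grid), so
components are estimable per subject. The planted effect is deliberately
placed on the *weakest* component: the headline result this mirrors is that
the third, smallest-variance signature classifies best, so variance
explained and diagnostic relevance need not coincide.

## What passing tests do and do not show

The generator realizes exactly the model the analysis assumes — linear
condition effects, stationary AR(1) noise, a single cosine drift, motion as
pure nuisance, orthogonal spatial maps shared across subjects. Passing
recovery and calibration tests therefore demonstrates internal correctness
and statistical calibration of the pipeline, not robustness to hemodynamic
nonlinearity, spatially correlated or nonstationary noise, motion-induced
signal artifacts, imperfect normalization, or subject-specific functional
anatomy, none of which are simulated.

## Numerical choices

- `inverse_sqrt_psd`: eigenvalues below 1e-12 of the maximum are treated as
  zero (pseudo-inverse square root); asymmetry beyond 1e-10 and negative
  eigenvalues are errors.
- SVD determinism: near-degenerate singular values (relative gap < 1e-8)
  are ordered by the first nonzero element of the left singular vector;
  each left vector's largest-magnitude entry is made positive, with the
  right vector flipped jointly.
- Correlation t maps: voxels constant across subjects get T = 0 (counted),
  |r| = 1 voxels are capped at T = 1e8 (counted).
- LDA: the pooled covariance gets a relative ridge of 1e-8 only if its
  Cholesky factorization fails; folds are redrawn (up to 100 times) if a
  training fold has fewer than two members of a class — impossible with
  stratified folds at the default sizes.
- Quantiles: linear-interpolation (type 7) definition.
- AR(1) is estimated once per subject, pooled over voxels, from OLS
  residuals; the pooled estimate at the defaults is biased low by ~0.04
  (the residual-forming projection absorbs low-frequency noise power),
  which stays within the ±0.05 calibration band and affects the whitener
  only smoothly.
- Whether the original analysis whitened with AR(1) or identity covariance
  is not documented; both are supported (`sigma = "ar1"` default,
  `"identity"` available). Voxel time courses are mean-centered by default
  (equivalent to the intercept regressor).

## Problem sizes used by the test-suite

Unit and property tests run on reduced grids (6×6×6 to 12×12×8) with the
full 352-scan paradigm; the end-to-end recovery check uses the full default
cohort (30 subjects, 16×16×8, 352 scans); the null-calibration study uses
50 cohorts at 12×12×8. The recovery property for point-biserial
correlations is stated at noise_sd = 0.25 and subject jitter 5: with the
study's Table-1 demographics, age and sex correlate with diagnosis
(R² ≈ 0.19), so confound removal necessarily absorbs part of any real group
difference and caps the attainable loading–label correlation near 0.9; the
stated SNR keeps the planted effect clearly above that ceiling.

## Known limitations

- One run per subject; no slice-timing, smoothing, or normalization — the
  package starts from preprocessed, mask-aligned volumes.
- The group MLM is run once per component rank (three signatures), which
  matches the reported per-signature loadings and classifiers; a single
  decomposition of all stacked components is not implemented.
- Signature t maps are descriptive and uncorrected by design; no
  multiple-comparison machinery is included.
- With voxels ≫ subjects the full-sample subject loadings are descriptive
  only; any inferential use must go through the fold-wise estimates, as the
  classifier does.
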