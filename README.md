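# mlmfmri

Two-level multivariate linear model (MLM) analysis of block-design task
fMRI, for researchers who want to extract cohort-level brain signatures
from condition-locked activity and test whether they separate diagnostic
groups — here schizophrenia versus recurrent depression, scanned during a
paranoid-depressive self-rating paradigm (depression-specific, paranoia-
specific and diagnostically neutral statements in 32 s blocks).

## The method

Per subject, with `Y` the scans × voxels BOLD matrix and `Xc` the three
HRF-convolved condition regressors (motion, drift and intercept partialled
out of both), the individual MLM decomposes the whitened cross-covariance

```
Z = (Xc' Σ Xc)^(-1/2) Xc' Y = U Λ V'
```

with `Σ` an AR(1) temporal covariance estimated from the GLM residuals.
`U` holds condition-space *clinical loadings*, `V` unit-norm *eigenimages*.
After sign-aligning components across subjects, each rank's eigenimages are
stacked (eigenvalue-weighted), age and sex are residualized out, and the
group MLM `Z_G = (X_G' X_G)^(-1/2) X_G' Y_G = U_G Λ_G V_G'` yields one
*brain signature* per component rank plus scalar *subject loadings* (the
projection of each subject's image onto the signature). A linear
discriminant on each rank's loadings, under stratified 2-fold
cross-validation repeated 100 times (signature re-estimated inside every
training fold to avoid circularity), quantifies how well that signature
separates the groups; signatures are visualized as voxelwise correlation
t maps (df = s − 2; at 30 subjects the one-sided p < 0.05 threshold is
T > 1.70).

A fully seeded synthetic-cohort generator (`simulate_cohort()`) reproduces
the study conditions — 16/14 subjects, 10M/6F vs 5M/9F, ages 36.4/45.3 ±
12.5 truncated to 18–65, a 704 s paradigm at TR = 2 s (352 scans), AR(1)
noise, cosine drift — and plants group amplitude differences that are
confined to chosen component ranks by construction, so every stage is
testable without any data download.

## Worked example

```r
library(mlmfmri)

cohort <- simulate_cohort(cohort_config(seed = 11))   # in memory
res    <- analyze_cohort(cohort, seed = 5)
res
#> two-level MLM pipeline: 30 subjects, 3 components
#>   signature 1: median CV accuracy 0.567 [0.467, 0.600], AUC 0.487
#>   signature 2: median CV accuracy 0.567 [0.500, 0.600], AUC 0.603
#>   signature 3: median CV accuracy 0.900 [0.867, 0.933], AUC 0.911
```

The default cohort plants its group difference in component rank 3 only,
and that is what the analysis finds: signatures 1 and 2 (which explain the
most variance) classify at chance, while signature 3 reaches a median
cross-validated accuracy of 0.90 — the configuration mirrors the finding
that the smallest-variance signature discriminates best. The recovered
rank-3 signature matches the planted group-difference map:

```r
sig <- res$groups[[3]]$signature
truth <- cohort$truth$group_difference_map
abs(sum(sig * truth)) / sqrt(sum(sig^2) * sum(truth^2))
#> [1] 0.853
```

`simulate_cohort(cfg, dir = "cohort/")` writes NIfTI volumes, SPM-style
motion files and a `participants.tsv`; `run_pipeline("cohort/participants.tsv",
"out/")` runs the same analysis from disk and writes signatures and t maps
(NIfTI), loading tables (TSV), classification summaries (JSON) and a
provenance record. Demographic tables are checked with
`chi_square_2x2()` — for the study's sex distribution,
`chi_square_2x2(rbind(c(10, 6), c(5, 9)))` gives p = 0.143.

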