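---
title: "Longitudinal multimodal prediction of clinical decline: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal multimodal prediction of clinical decline: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Mild cognitive impairment (MCI) is a prodromal stage of Alzheimer's disease
(AD). Two clinical questions dominate its follow-up: will a given patient
convert to AD (a classification problem), and what will their cognitive
scores — MMSE (0–30, lower is worse) and ADAS-Cog (higher is worse) — be at a
future visit (a regression problem)? Most predictive models use baseline
imaging only, yet MCI cohorts are followed longitudinally: regional MRI
volumes and FDG-PET intensities are measured repeatedly at 6-month visits.
`longipred` implements a three-stage pipeline that exploits those repeated
measures:

1. **joint region selection across time points** with an $\ell_{2,1}$
   row-group penalty,
2. **polynomial trajectory coefficients** as explicit longitudinal features,
3. **multi-kernel SVM fusion** of imaging modalities and cognitive scores.

The package operates on regional feature tables (one value per subject,
modality, visit and region); image acquisition, registration and ROI
labelling are upstream and out of scope.

## Stage 1: group-temporal selection

At every visit $j = 1..T$ a sparse linear model relates the $N \times D$
regional feature matrix $X^j$ to that visit's clinical target $y^j$ (the
same-visit score for regression, the converter label for classification).
The $T$ per-visit weight vectors form the columns of a $D \times T$ matrix
$W$, penalized by rows:

$$ \min_W \;\sum_{j=1}^{T} \lVert y^j - X^j w^j \rVert_2^2
   \;+\; \lambda \sum_{d=1}^{D} \lVert W_{d\cdot} \rVert_2 . $$

The $\ell_{2,1}$ term couples region $d$'s weights across all visits: a
region is kept or discarded *jointly* over time, which is what makes the
selection longitudinal rather than per-visit. With $T = 1$ the model is the
ordinary Lasso. No $1/2$ or $1/N$ factor is used in the loss; the $\lambda$
grid is expressed relative to the critical value
$\lambda_{\max} = 2 \max_d \lVert (x_d^{1\top} y^1, \dots,
x_d^{T\top} y^T) \rVert_2$, above which $W = 0$ exactly, so the convention
is internally consistent.

**Solver.** `gtl_fit()` runs FISTA (accelerated proximal gradient) with
backtracking line search and a monotone restart; the proximal map of the
penalty is row-wise block soft-thresholding (`prox_l21()`). Defaults:
relative-objective tolerance `1e-6`, at most 5000 iterations. Targets are
centered internally; intercepts are restored at prediction. Rows whose norm
survives `1e-8` are reported selected — prox-zeroed rows are exact zeros, so
the threshold is not delicate. The test suite checks the solver against an
independent projected-gradient oracle on the smooth second-order-cone
epigraph reformulation, and against coordinate-descent Lasso at $T = 1$.

**Choosing $\lambda$.** `gtl_select_lambda_cv()` scores a 20-point
log-spaced grid on $[\lambda_{\max}/100, \lambda_{\max}]$ by inner-CV
held-out RMSE averaged over visits. Penalties within one standard error of
the minimizer are treated as tied and the tie breaks toward the largest —
the classical one-SE rule. The strict arg-min is available
(`se_factor = 0`) but over-selects badly on flat CV curves: under a
pure-noise target it picks an arbitrary grid point, while the one-SE rule
drives the selection to the empty model, which is the correct null
behavior. A consequence worth knowing: on cohorts where baseline imaging is
only weakly related to the target, the selected baseline-only model is often
empty — the pipeline then rides on the remaining kernels (see fusion below),
which we consider honest rather than a defect.

## Stage 2: longitudinal trajectory features

For each selected region, each subject's $T$ values are interpolated exactly
by the degree-$(T-1)$ polynomial
$u(t) = c_0 + c_1 t + \dots + c_{T-1} t^{T-1}$ at the integer visit codes
$t = 1..T$, solved through the $T \times T$ Vandermonde system
(`fit_poly_coeffs()`). The coefficients are the longitudinal features:
$c_1$ generalizes the familiar two-point "thinning speed", higher orders
capture curvature. With $T \le 5$ visits the monomial basis is perfectly
well-conditioned; a warning is issued beyond $T = 8$. The degree is always
$T - 1$ (an exactly determined system); a lower-degree least-squares option
was considered and rejected as a default because exact interpolation is the
defining property asserted by the package's tests.

The final per-modality vector concatenates the selected raw values at all
visits with all polynomial coefficients, region-major
(`assemble_modality_matrix()`). The two blocks are linearly redundant — the
coefficients determine the raw values exactly — but the fused model
concatenates both by design; the SVM's regularization tolerates the
redundancy, and keeping both preserves the interpretation of each block.
Cognitive scores form their own "modality": the scores at all used visits,
concatenated, with no selection and no interpolation.

## Stage 3: multi-kernel fusion

Each modality's vectors are z-scored per column (training statistics only;
population-SD convention, constant columns floored at `1e-8`), unit-normed
per subject, and turned into a linear Gram matrix, so each kernel is a
cosine similarity with unit diagonal. The fused kernel is the convex
combination $k = \sum_m \beta_m k_m$, $\beta_m \ge 0$, $\sum_m \beta_m = 1$,
handed to a conventional SVM solver in precomputed-kernel mode
(`kernlab::ksvm`, C-SVC for classification, $\varepsilon$-SVR with
$\varepsilon = 0.1$ on z-scored targets for regression). $(\beta, C)$ are
chosen by seeded inner cross-validation over the full simplex grid
(step 0.1 by default) and a cost grid $2^{-5}, 2^{-3}, \dots, 2^5$; ties
break toward the more uniform $\beta$, then the smaller $C$. Decision values
(signed margins) feed the ROC; they are the only natural score an SVM
offers. One-hot $\beta$ reproduces the corresponding single-modality model
bit-for-bit — a degeneracy the acceptance tests assert at `1e-9`.

## Evaluation protocols

*Score regression* uses stratified k-fold cross-validation repeated
`runs` times (default 10 × 10): all stages — normalization, selection,
trajectory features, the $(\beta, C)$ search — are fitted inside each
training fold. CORR (Pearson) and RMSE are computed per fold and averaged
(the pooled-prediction variant is also reported, and both are kept because
fold-averaged correlations on small folds are noisy but match the
convention of reporting mean ± SD over folds).

*Conversion classification* uses leave-one-out with flexible horizons: a
converter's usable data end one visit (6 months) before conversion
(`truncate_to_horizon()`), non-converters are capped at the penultimate
visit. For a test subject with horizon $T_s$ the training set is the other
subjects whose own horizon reaches $T_s$, truncated to exactly $T_s$ visits,
and the entire pipeline is refitted — the only reading of the
flexible-horizon setting that is both rectangular and leakage-free. The
alternative (train once at maximal $T$) would either leak post-horizon data
or require imputation the model does not define.

*Region reporting*: `region_selection_frequency()` counts how often each
region is selected across all folds and runs and reports the top 20% (ties
broken alphabetically and flagged).

## The synthetic cohort generator

Real ADNI data are access-restricted, so `generate_cohort()` produces
cohorts with the same shape and known ground truth: 88 subjects (38
converters / 50 non-converters), MRI and PET with 93 regions each, 5 visits,
MMSE-like and ADAS-Cog-like scores. Structure:

- A small informative subset of regions per modality (10, half shared
  between modalities to emulate complementary information). Half of each
  informative set drives the MMSE-like score, half the ADAS-Cog-like score.
- Informative regions follow group-specific linear trajectories around
  subject-specific baselines; all other regions are stationary noise.
  Group offsets and slopes are solved analytically from group-mean anchors
  (converters ≈ 26.9 → 23.9 MMSE over 24 months, non-converters
  ≈ 27.4 → 27.0; 12.7 → 16.1 and 9.6 → 11.0 for ADAS-Cog), so generated
  group means land near those anchors by construction. The anchors are soft
  calibration targets: the generator never claims to reproduce real-cohort
  numbers.
- **Per-subject decline rates.** Every subject carries a rate multiplier
  (mean 1, SD `subject_slope_sd = 0.6`) on all its informative-region
  slopes. Decline-rate heterogeneity is characteristic of MCI cohorts — the
  follow-up spread of scores fans out over time (the emulated cohort's
  24-month MMSE SD roughly doubles its baseline SD) — and it is precisely
  what makes longitudinal visits informative beyond baseline: with a single
  shared group slope, baseline group separation alone would saturate the
  predictable signal.
- Scores are exact affine functions of the informative region values plus
  Gaussian noise, clipped to [0, 30] (MMSE-like) or at 0 (ADAS-Cog-like),
  so with all noise at zero the score model is recoverable to machine
  precision — a generator invariant the tests assert.
- Converters draw a conversion time over months 6–48; horizon truncation
  then yields the flexible-$T$ classification setting.

What the generator does **not** emulate: spatial correlation between
regions, scanner and site effects, heavy-tailed or missing-not-at-random
measurements, practice effects on cognitive tests, and any nonlinear
score–biomarker link. Synthetic results therefore demonstrate correctness
and qualitative behavior of the pipeline, not expected real-data
performance; in particular the clean affine score model makes synthetic
classification much easier than the real task.

## Problem sizes and numerical choices in the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) scale
the protocols to desk size, as a design choice documented here: 5-fold CV
with 2 runs instead of 10 × 10, a 10-point $\lambda$ grid, simplex step 0.5,
cost grid $\{0.5, 4, 32\}$, and inner 5-fold CV for $\lambda$ (3 folds
inflate the one-SE band and over-prune). The longitudinal-benefit experiment
uses "progressive-signal" cohorts with feature noise SD 0.75, i.e. a
per-visit trajectory increment about equal to the noise, so each added visit
carries real incremental signal. With those settings the qualitative
pattern of the reference setting reproduces: mean CV correlation is
non-decreasing in the number of visits for 8 of 10 seeded cohorts (one
cohort's imaging selection is empty through two visits and dips; one dips
by 0.007), and the fused longitudinal model beats baseline-only CONCAT and
Ensemble in 10 of 10.

Other numerical details, gathered: population (1/N) SD in z-scoring;
SD floor `1e-8`; solver tolerance `1e-6` relative, `max_iter` 5000;
selection threshold `1e-8` on row norms; SVM solver tolerance `1e-6` with
shrinking off, so repeated runs agree to `1e-9`; majority-vote ties break by
mean decision score, then toward non-converter; empty selections fall back
to a constant (mean / majority) predictor rather than an error.

## Open interpretation points, decided

- Whether z-scoring precedes trajectory extraction is not prescribed
  anywhere; we z-score raw regional features first, then interpolate, which
  keeps the coefficient scales comparable across regions.
- Selection is fitted once per target score (one for MMSE, one for
  ADAS-Cog), not as a multi-target variant; the per-score models are
  independent.
- The $(\beta, C)$ search runs inside every outer training fold
  (leakage-free), not once globally.
- The Ensemble baseline groups both cognitive scores into one block per
  time point.

## Known limitations

Interior missing visits are rejected rather than imputed (only trailing
truncation is modeled). Temporal-smoothness coupling between adjacent
visits' weights is not implemented. $\beta$ is grid-searched, not optimized
by convex multiple-kernel learning. Nonlinear kernels and probability
calibration are out of scope.
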