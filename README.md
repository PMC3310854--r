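# longipred

Longitudinal multimodal prediction of clinical decline in mild cognitive
impairment (MCI): future cognitive scores (MMSE, ADAS-Cog) by support-vector
regression, and conversion to Alzheimer's disease by classification, from
regional biomarkers (e.g. MRI volumes, FDG-PET intensities) measured at
repeated 6-month visits.

The package is for methodologists and applied groups working with
longitudinal cohort tables: one value per (subject, modality, visit,
region), plus per-visit clinical scores and a converter label. Imaging
preprocessing (registration, ROI labelling) is upstream and out of scope.

## The method

Three stages, each fitted strictly inside the training data:

1. **Joint region selection across visits.** One sparse linear model per
   visit, coupled by an ℓ2,1 row-group penalty on the D×T weight matrix W
   (rows = regions, columns = visits):

       min over W of  Σ_j ‖y_j − X_j w_j‖² + λ Σ_d ‖W_d·‖₂

   Whole rows of W vanish, so a region is kept or dropped jointly across
   all visits. Solved by FISTA with backtracking and monotone restart; λ by
   inner cross-validation with the one-standard-error rule. With T = 1 this
   is the ordinary Lasso.

2. **Trajectory features.** For each selected region, the subject's T values
   are interpolated exactly by a degree-(T−1) polynomial at visit codes
   t = 1..T (Vandermonde solve); the coefficients c₀..c_{T−1} — intercept,
   slope, curvature, … — are appended to the raw values.

3. **Multi-kernel SVM fusion.** Per modality (each imaging modality, plus
   the cognitive scores as their own modality), vectors are z-scored,
   unit-normed, and turned into linear kernels; the fused kernel
   k = Σ_m β_m k_m (β on the simplex) is trained with a conventional SVM
   solver in precomputed-kernel mode. (β, C) come from an inner-CV grid
   search.

Evaluation harnesses implement repeated stratified k-fold CV for score
regression (CORR/RMSE per fold) and flexible-horizon leave-one-out for
conversion (accuracy, sensitivity, specificity, AUC, ROC), plus region
selection frequency reporting and the CONCAT / Ensemble / single-modality
comparison baselines. A seeded synthetic-cohort generator with known ground
truth (informative regions, true score model, conversion times) makes every
stage testable without restricted data; see the methods vignette
(`vignettes/longipred-methods.Rmd`) for the generative model and its limits.

## Worked example

```r
library(longipred)

cohort <- generate_cohort(synthetic_config(seed = 42))
print(cohort$dataset)
#> longitudinal_dataset: 88 subjects, 5 time points ( bl, M06, M12, M18, M24 )
#>   modality MRI : 93 regions
#>   modality PET : 93 regions
#>   scores: MMSE, ADAS
#>   labels: 38 converters / 50 non-converters

ctl <- pipeline_control(n_lambda = 10, inner_folds = 3, beta_step = 0.5,
                        C_grid = c(0.5, 4, 32))
report <- run_regression_cv(cohort$dataset, method = "proposed",
                            target_score = "MMSE", k = 5, runs = 1,
                            seed = 1, control = ctl)
print(report)
#> evaluation_report [proposed, MMSE @ t=5]: CORR 0.805 +/- 0.056, RMSE 1.470 +/- 0.132 (5-fold x 1 runs)

freq <- region_selection_frequency(report, region_names = cohort$dataset$region_names)
head(freq$MRI$table, 5)
#>    region frequency
#> 1 MRI_R18         1
#> 2 MRI_R20         1
#> 3 MRI_R25         1
#> 4 MRI_R37         1
#> 5 MRI_R47         1

cohort$dataset$region_names$MRI[cohort$truth$informative$MRI]
#> "MRI_R18" "MRI_R24" "MRI_R25" "MRI_R37" "MRI_R47" "MRI_R49" "MRI_R65" "MRI_R71" "MRI_R74" "MRI_R93"
```

Reading this: predicting the 24-month MMSE-like score from the four earlier
visits reaches a mean per-fold Pearson correlation of 0.805 (SD over folds
0.056) and RMSE 1.470 score points on this synthetic cohort, and the regions
selected in every training fold (frequency 1) are dominated by the
generator's truly informative ones (4 of the top 5 here).

Conversion classification uses the flexible-horizon protocol: truncate each
converter to one visit before conversion, then leave-one-out:

```r
clf_data <- truncate_to_horizon(cohort$dataset, cohort$truth)
clf <- run_classification_loocv(clf_data, method = "proposed", seed = 1,
                                control = ctl)
```

## Command line

A thin CLI over the same functions ships in `inst/cli/longipred.R`
(subcommands `simulate`, `select`, `extract`, `run`, `compare`):

```sh
Rscript inst/cli/longipred.R simulate --out cohort/ --seed 17
Rscript inst/cli/longipred.R run --simulate --task regression --k 5 --runs 1 \
    --seed 17 --out results/run1
```

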