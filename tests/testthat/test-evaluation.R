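test_that("regression metrics match hand calculations and brute force", {
  y <- c(1, 2, 3)
  expect_equal(pearson_corr(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(pearson_corr(y - 2, -(y - 2)), -1)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3), tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), y), "zero-variance")
  expect_error(pearson_corr(1, 1), "at least 2")
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(20); b <- rnorm(20) + 0.5 * a
    expect_equal(pearson_corr(a, b), bf_corr(a, b), tolerance = 1e-12)
    expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  }
})

test_that("confusion metrics follow the converter convention", {
  expect_equal(confusion_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1)),
               c(accuracy = 0.75, sensitivity = 0.5, specificity = 1.0))
  lab <- c(1, -1, 1, -1, 1)
  expect_equal(unname(confusion_metrics(lab, lab)), c(1, 1, 1))
  expect_equal(unname(confusion_metrics(lab, -lab)), c(0, 0, 0))
  # absent class is undefined, not zero
  expect_true(is.na(confusion_metrics(c(1, 1), c(1, -1))[["specificity"]]))
  for (s in 1:100) {
    set.seed(s)
    lab <- sign(rnorm(30)); prd <- sign(rnorm(30))
    expect_equal(confusion_metrics(lab, prd), bf_confusion(lab, prd),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the all-pairs count with half ties", {
  expect_equal(roc_auc(c(1, -1, 1, -1), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, -1, -1), c(2, 1.5, 1, 0.5))$auc, 1)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
  for (s in 1:100) {
    set.seed(s)
    lab <- c(rep(1, 8), rep(-1, 12))
    sc <- round(rnorm(20), 1)  # force some ties
    expect_equal(roc_auc(lab, sc)$auc, bf_auc(lab, sc), tolerance = 1e-12)
  }
  # label-independent scores hover near 1/2
  set.seed(99)
  lab <- c(rep(1, 500), rep(-1, 500))
  expect_lt(abs(roc_auc(lab, rnorm(1000))$auc - 0.5), 0.06)
  # ROC endpoints
  r <- roc_auc(c(1, -1, 1, -1), c(0.9, 0.8, 0.7, 0.1))$roc
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[nrow(r)], r$fpr[nrow(r)]), c(1, 1))
})

test_that("fold partitions are disjoint, exhaustive, reproducible and stratified", {
  lab <- c(rep(1, 17), rep(-1, 25))
  f1 <- make_folds(42, 10, labels = lab, seed = 7)
  f2 <- make_folds(42, 10, labels = lab, seed = 7)
  f3 <- make_folds(42, 10, labels = lab, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_setequal(unique(f1), 1:10)
  expect_equal(length(f1), 42L)
  # each stratum spreads evenly (within one) across folds
  pos_per_fold <- table(factor(f1[lab == 1], levels = 1:10))
  neg_per_fold <- table(factor(f1[lab == -1], levels = 1:10))
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1L)
  expect_lte(max(neg_per_fold) - min(neg_per_fold), 1L)
  # calling make_folds must not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(make_folds(20, 4, seed = 3)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("training-side fits ignore the test fold entirely (leakage guard)", {
  ch <- quick_cohort(seed = 31)
  tr <- subset_dataset(ch$dataset, 1:30)
  te1 <- subset_dataset(ch$dataset, 31:40)
  te2 <- te1
  for (m in te2$modalities) te2$features[[m]][] <- 99  # vandalize test features
  te2$scores[] <- 99
  ctl <- quick_control()
  r1 <- proposed_fit_predict(tr, te1, "regression", control = ctl, seed = 5)
  r2 <- proposed_fit_predict(tr, te2, "regression", control = ctl, seed = 5)
  expect_identical(serialize(r1$fit, NULL), serialize(r2$fit, NULL))
  rc1 <- concat_fit_predict(tr, te1, "regression", control = ctl, seed = 5)
  rc2 <- concat_fit_predict(tr, te2, "regression", control = ctl, seed = 5)
  expect_identical(serialize(rc1$fit$selection, NULL),
                   serialize(rc2$fit$selection, NULL))
})

test_that("repeated CV aggregates per-fold metrics and records selections", {
  ch <- quick_cohort(seed = 32, n = 30L, conv = 13L)
  ctl <- quick_control()
  rep1 <- run_regression_cv(ch$dataset, "proposed", target_score = "MMSE",
                            k = 3L, runs = 2L, seed = 11, control = ctl)
  expect_equal(nrow(rep1$folds), 6L)
  expect_true(all(rep1$folds$rmse >= 0))
  expect_true(abs(rep1$corr_mean) <= 1)
  expect_length(rep1$selections, 6L)
  # determinism: same seed, same report
  rep2 <- run_regression_cv(ch$dataset, "proposed", target_score = "MMSE",
                            k = 3L, runs = 2L, seed = 11, control = ctl)
  expect_equal(rep1$folds, rep2$folds)
  expect_equal(rep1$predictions, rep2$predictions)
})

test_that("permuted targets yield correlations near zero", {
  corrs <- vapply(1:5, function(s) {
    ch <- quick_cohort(seed = 500 + s, n = 30L, conv = 13L)
    ds <- ch$dataset
    set.seed(s)
    perm <- sample(n_subjects(ds))
    ds$scores[, 5L, "MMSE"] <- ds$scores[perm, 5L, "MMSE"]
    run_regression_cv(ds, "proposed", target_score = "MMSE", k = 3L,
                      runs = 1L, seed = s, control = quick_control())$corr_mean
  }, numeric(1L))
  se <- sd(corrs) / sqrt(length(corrs))
  expect_lt(abs(mean(corrs)), 3 * max(se, 0.1))
})

test_that("flexible-horizon LOOCV is deterministic and classifies a separable cohort", {
  ch <- quick_cohort(seed = 33, n = 24L, conv = 11L, noise = 0.3,
                     score_noise_sd = 0.3)
  ds <- truncate_to_horizon(ch$dataset, ch$truth)
  ctl <- quick_control()
  r1 <- run_classification_loocv(ds, "proposed", seed = 2, control = ctl,
                                 min_train = 5L)
  r2 <- run_classification_loocv(ds, "proposed", seed = 2, control = ctl,
                                 min_train = 5L)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$decisions, r2$decisions)
  expect_gte(r1$accuracy, 0.75)  # low-noise cohort separates well
  expect_true(r1$auc >= 0 && r1$auc <= 1)
})

test_that("selection frequencies respect the accounting identity and rank truth highly", {
  ch <- quick_cohort(seed = 34, n = 40L, conv = 18L, noise = 0.4)
  rep1 <- run_regression_cv(ch$dataset, "proposed", target_score = "MMSE",
                            k = 4L, runs = 2L, seed = 3,
                            control = quick_control())
  fr <- region_selection_frequency(rep1, region_names = ch$dataset$region_names)
  total_folds <- 4L * 2L
  for (m in names(fr)) {
    n_sel <- vapply(rep1$selections, function(s) length(s[[m]]$selected),
                    integer(1L))
    expect_equal(fr[[m]]$mean_selected_per_fold, mean(n_sel) ,
                 tolerance = 1e-12)
    expect_true(all(fr[[m]]$table$frequency >= 0 & fr[[m]]$table$frequency <= 1))
  }
  # a region selected in every fold has frequency exactly 1
  always <- lapply(rep1$selections, function(s) s$MRI$selected)
  common <- Reduce(intersect, always)
  if (length(common) > 0) {
    nm <- ch$dataset$region_names$MRI[common[1L]]
    expect_equal(fr$MRI$table$frequency[fr$MRI$table$region == nm], 1)
  }
})
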