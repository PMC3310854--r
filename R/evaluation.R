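#' Pearson correlation between truth and prediction
#'
#' @param y,yhat numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`; errors on zero-variance input.
#' @export
pearson_corr <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (pop_sd(y) == 0 || pop_sd(yhat) == 0)
    stop("undefined correlation: zero-variance input", call. = FALSE)
  stats::cor(y, yhat)
}

#' Root mean square error
#'
#' @param y,yhat numeric vectors of equal length >= 1.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1L) stop("empty input", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Convention: +1 = converter. Sensitivity is the proportion of converters
#' correctly identified, specificity the proportion of non-converters. A
#' metric whose class is absent from the labels is `NA` (undefined), not 0.
#'
#' @param labels,preds vectors in `{+1, -1}`.
#' @return named vector `(accuracy, sensitivity, specificity)`.
#' @export
confusion_metrics <- function(labels, preds) {
  if (length(labels) != length(preds)) stop("length mismatch", call. = FALSE)
  if (!all(c(labels, preds) %in% c(-1, 1)))
    stop("labels and predictions must be in {+1, -1}", call. = FALSE)
  pos <- labels == 1
  c(accuracy = mean(preds == labels),
    sensitivity = if (any(pos)) mean(preds[pos] == 1) else NA_real_,
    specificity = if (any(!pos)) mean(preds[!pos] == -1) else NA_real_)
}

#' ROC curve and area under it
#'
#' AUC is computed as the Mann-Whitney rank statistic (ties between a
#' converter and a non-converter score count 1/2), equivalently the
#' probability that a random converter outscores a random non-converter.
#' ROC points are swept over all unique score thresholds plus the two
#' degenerate endpoints.
#'
#' @param labels vector in `{+1, -1}`, both classes present.
#' @param scores numeric decision scores (larger = more converter-like).
#' @return list with `auc` and `roc`, a data.frame of (fpr, tpr) points.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC requires both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(
    threshold = thresholds,
    tpr = vapply(thresholds, function(th) mean(scores[pos] >= th), numeric(1L)),
    fpr = vapply(thresholds, function(th) mean(scores[!pos] >= th), numeric(1L)))
  list(auc = auc, roc = roc)
}

#' Seed-reproducible (optionally stratified) fold assignment
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param labels optional vector; folds are stratified by its values.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, each subject in exactly one.
#' @export
make_folds <- function(n, k, labels = NULL, seed = 1L) {
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  set.seed(seed)
  fold <- integer(n)
  if (is.null(labels)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      # rotate start so small strata don't all land in fold 1
      start <- sample.int(k, 1L)
      ids <- (rep_len(seq(start, length.out = length(idx)), length(idx)) - 1L) %% k + 1L
      fold[idx] <- sample(ids)
    }
  }
  fold
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# dispatch one train/test fit for a named method
method_fit_predict <- function(method, train, test, task, target_score,
                               target_time, time_points, control, seed,
                               modality = NULL) {
  switch(method,
    proposed = proposed_fit_predict(train, test, task, target_score,
                                    target_time, time_points,
                                    control = control, seed = seed),
    concat = concat_fit_predict(train, test, task, target_score, target_time,
                                time_points, control = control, seed = seed),
    ensemble = ensemble_fit_predict(train, test, task, target_score,
                                    target_time, time_points,
                                    control = control, seed = seed),
    single = single_modality_fit_predict(train, test, task,
                                         modality = modality,
                                         target_score = target_score,
                                         target_time = target_time,
                                         time_points = time_points,
                                         control = control, seed = seed),
    stop("unknown method: ", method, call. = FALSE))
}

#' Repeated k-fold cross-validated score regression
#'
#' The first validation protocol: predict a future clinical score (by
#' default, the last visit's) from all earlier time points with k-fold
#' cross-validation repeated `runs` times, reporting Pearson correlation and
#' RMSE per fold, their mean and standard deviation over folds/runs
#' (fold-averaged, with the pooled-prediction variant also reported), and
#' the per-fold region selections for frequency analysis. Folds are
#' stratified by converter label when labels are present. Every pipeline
#' stage is fitted inside the training folds only.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param method `"proposed"`, `"concat"`, `"ensemble"` or `"single"`.
#' @param target_score score to predict.
#' @param target_time time code of the prediction target (default: last).
#' @param time_points leading input time codes (default: all before
#'   `target_time`).
#' @param k folds per run.
#' @param runs independent repetitions.
#' @param seed master seed; run r uses fold seed `seed + r`.
#' @param control a [pipeline_control()].
#' @param modality for `method = "single"`.
#' @return an `evaluation_report` list.
#' @export
run_regression_cv <- function(dataset, method = "proposed",
                              target_score = "MMSE", target_time = NULL,
                              time_points = NULL, k = 10L, runs = 10L,
                              seed = 1L, control = pipeline_control(),
                              modality = NULL) {
  tt_all <- length(dataset$time_codes)
  if (is.null(target_time)) target_time <- tt_all
  if (is.null(time_points)) time_points <- seq_len(target_time - 1L)
  n <- n_subjects(dataset)
  y_true <- dataset$scores[, target_time, target_score]
  fold_rows <- list()
  pooled_pred <- list()
  selections <- list()
  for (r in seq_len(runs)) {
    fold_id <- make_folds(n, k, labels = dataset$labels, seed = seed + r)
    pred_run <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      te_idx <- which(fold_id == f)
      tr_idx <- which(fold_id != f)
      res <- method_fit_predict(method,
                                subset_dataset(dataset, tr_idx),
                                subset_dataset(dataset, te_idx),
                                task = "regression",
                                target_score = target_score,
                                target_time = target_time,
                                time_points = time_points,
                                control = control,
                                seed = seed + 1000L * r + f,
                                modality = modality)
      pred_run[te_idx] <- res$prediction
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        run = r, fold = f,
        corr = tryCatch(pearson_corr(y_true[te_idx], res$prediction),
                        error = function(e) NA_real_),
        rmse = rmse(y_true[te_idx], res$prediction))
      if (!is.null(res$fit$selections))
        selections[[length(selections) + 1L]] <- res$fit$selections
    }
    pooled_pred[[r]] <- pred_run
  }
  folds_df <- do.call(rbind, fold_rows)
  pooled_corr <- vapply(pooled_pred, function(p) pearson_corr(y_true, p),
                        numeric(1L))
  pooled_rmse <- vapply(pooled_pred, function(p) rmse(y_true, p), numeric(1L))
  structure(list(
    task = "regression", method = method, target_score = target_score,
    target_time = target_time, time_points = time_points,
    k = k, runs = runs, seed = seed,
    folds = folds_df,
    corr_mean = mean(folds_df$corr, na.rm = TRUE),
    corr_sd = stats::sd(folds_df$corr, na.rm = TRUE),
    rmse_mean = mean(folds_df$rmse),
    rmse_sd = stats::sd(folds_df$rmse),
    pooled_corr = mean(pooled_corr), pooled_rmse = mean(pooled_rmse),
    predictions = pooled_pred, y_true = y_true,
    selections = selections,
    config = list(control = unclass(control))),
    class = "evaluation_report")
}

#' Leave-one-out cross-validated conversion classification
#'
#' The second validation protocol: each subject is left out in turn and
#' predicted as converter / non-converter from its usable time points
#' (`subject_T`, typically set by [truncate_to_horizon()] to end one step
#' before conversion). For a test subject with horizon `T_s`, the training
#' set is the other subjects whose own horizon reaches `T_s`, truncated to
#' exactly the first `T_s` time points, and the entire pipeline is re-fitted
#' — a leakage-free reading of the flexible-horizon setting.
#'
#' @param dataset a labelled `longitudinal_dataset` with `subject_T` set.
#' @param method as in [run_regression_cv()].
#' @param seed master seed for inner cross-validations.
#' @param control a [pipeline_control()].
#' @param modality for `method = "single"`.
#' @param min_train minimum usable training subjects per left-out subject.
#' @return an `evaluation_report` with accuracy, sensitivity, specificity,
#'   AUC, ROC points and per-subject predictions.
#' @export
run_classification_loocv <- function(dataset, method = "proposed", seed = 1L,
                                     control = pipeline_control(),
                                     modality = NULL, min_train = 10L) {
  if (is.null(dataset$labels))
    stop("classification requires labels", call. = FALSE)
  n <- n_subjects(dataset)
  preds <- rep(NA_real_, n)
  decisions <- rep(NA_real_, n)
  horizons <- dataset$subject_T
  for (i in seq_len(n)) {
    ts <- horizons[i]
    pool <- setdiff(which(horizons >= ts), i)
    if (length(pool) < min_train)
      stop("too few training subjects with horizon >= ", ts,
           " for subject ", dataset$subject_ids[i], call. = FALSE)
    if (length(unique(dataset$labels[pool])) < 2L)
      stop("single-class training pool at horizon ", ts, call. = FALSE)
    train <- subset_dataset(dataset, pool, time_points = seq_len(ts))
    test <- subset_dataset(dataset, i, time_points = seq_len(ts))
    res <- method_fit_predict(method, train, test,
                              task = "classification",
                              target_score = NULL, target_time = NULL,
                              time_points = seq_len(ts),
                              control = control,
                              seed = seed + 17L * i,
                              modality = modality)
    preds[i] <- res$prediction$class
    decisions[i] <- res$prediction$decision
  }
  cm <- confusion_metrics(dataset$labels, preds)
  roc <- roc_auc(dataset$labels, decisions)
  structure(list(
    task = "classification", method = method, seed = seed,
    predictions = preds, decisions = decisions, labels = dataset$labels,
    subject_T = horizons,
    accuracy = cm[["accuracy"]], sensitivity = cm[["sensitivity"]],
    specificity = cm[["specificity"]], auc = roc$auc, roc = roc$roc,
    config = list(control = unclass(control))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$task == "regression") {
    cat(sprintf("evaluation_report [%s, %s @ t=%d]: CORR %.3f +/- %.3f, RMSE %.3f +/- %.3f (%d-fold x %d runs)\n",
                x$method, x$target_score, x$target_time,
                x$corr_mean, x$corr_sd, x$rmse_mean, x$rmse_sd, x$k, x$runs))
  } else {
    cat(sprintf("evaluation_report [%s, LOOCV]: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
                x$method, x$accuracy, x$sensitivity, x$specificity, x$auc))
  }
  invisible(x)
}

#' Region selection frequency across folds and runs
#'
#' Counts how often each region was selected across all folds of all runs of
#' one or more cross-validation reports and returns the per-modality
#' frequency table plus the top fraction (default 20%) by frequency, ties
#' broken alphabetically by region name and flagged.
#'
#' @param reports an `evaluation_report` (from a method that records
#'   selections) or a list of them.
#' @param region_names named list of region-name vectors per modality
#'   (optional; indices used otherwise).
#' @param top_fraction fraction of regions reported as "top" (default 0.2).
#' @return list per modality: data.frame `(region, frequency)` sorted by
#'   decreasing frequency, `top` region names, and `tie_at_cutoff` flag.
#' @export
region_selection_frequency <- function(reports, region_names = NULL,
                                       top_fraction = 0.2) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  sel_lists <- unlist(lapply(reports, function(r) r$selections),
                      recursive = FALSE)
  if (length(sel_lists) == 0L) stop("reports carry no selections", call. = FALSE)
  modalities <- names(sel_lists[[1L]])
  out <- list()
  for (m in modalities) {
    total <- length(sel_lists)
    d <- length(sel_lists[[1L]][[m]]$row_norms)
    counts <- numeric(d)
    for (s in sel_lists) counts[s[[m]]$selected] <- counts[s[[m]]$selected] + 1
    nms <- if (!is.null(region_names)) region_names[[m]] else
      sprintf("%s_%03d", m, seq_len(d))
    freq <- data.frame(region = nms, frequency = counts / total)
    freq <- freq[order(-freq$frequency, freq$region), ]
    rownames(freq) <- NULL
    n_top <- max(1L, floor(top_fraction * d))
    cutoff <- freq$frequency[n_top]
    tie <- n_top < d && freq$frequency[n_top + 1L] == cutoff && cutoff > 0
    out[[m]] <- list(table = freq, top = freq$region[seq_len(n_top)],
                     tie_at_cutoff = tie,
                     mean_selected_per_fold = sum(freq$frequency))
  }
  out
}
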