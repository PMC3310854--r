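#' Control parameters for the prediction pipelines
#'
#' Collects every tunable of the proposed method and the baselines in one
#' place, with the package defaults.
#'
#' @param n_lambda,lambda_min_ratio penalty grid: `n_lambda` log-spaced values
#'   in `[lambda_min_ratio * lambda_max, lambda_max]`.
#' @param inner_folds folds of the inner cross-validation used for both the
#'   penalty and the (beta, C) search.
#' @param beta_step simplex grid step for kernel weights.
#' @param C_grid SVM cost grid.
#' @param epsilon epsilon-SVR tube width (targets are z-scored internally).
#' @param tol,max_iter solver settings for [gtl_fit()].
#' @param use_poly include polynomial trajectory coefficients in the fused
#'   feature vectors (the proposed method does; disable for ablation).
#' @param use_cognitive include the cognitive-score modality.
#' @param lambda optional fixed selection penalty; `NULL` (default) selects
#'   it by inner cross-validation.
#' @return a `pipeline_control` list.
#' @export
pipeline_control <- function(n_lambda = 20L, lambda_min_ratio = 0.01,
                             inner_folds = 5L, beta_step = 0.1,
                             C_grid = 2^seq(-5, 5, 2), epsilon = 0.1,
                             tol = 1e-6, max_iter = 5000L,
                             use_poly = TRUE, use_cognitive = TRUE,
                             lambda = NULL) {
  structure(as.list(environment()), class = "pipeline_control")
}

# Extract the prediction target before any subsetting: score at target_time
# (regression) or the converter label (classification).
pipeline_target <- function(dataset, task, target_score, target_time) {
  if (task == "regression") {
    y <- dataset$scores[, target_time, target_score]
    if (anyNA(y)) stop("missing target scores at target_time", call. = FALSE)
    y
  } else {
    if (is.null(dataset$labels))
      stop("classification requires labels", call. = FALSE)
    dataset$labels
  }
}

# Per-time design/target lists for the group-temporal selection of one
# modality: X_j = z-scored regional features at time j; y_j = z-scored score
# at time j (regression) or the labels (classification).
selection_problem <- function(zds, modality, task, target_score) {
  fm <- zds$features[[modality]]
  tt <- dim(fm)[2L]
  n <- dim(fm)[1L]
  X <- lapply(seq_len(tt), function(j) matrix(fm[, j, ], n))
  y <- if (task == "regression")
    lapply(seq_len(tt), function(j) zds$scores[, j, target_score])
  else
    rep(list(as.numeric(zds$labels)), tt)
  list(X = X, y = y)
}

#' Fit the proposed method on a training set and predict a test set
#'
#' The full pipeline on one train/test split, every stage fitted on the
#' training subjects only:
#' 1. z-score each (modality, time, region) feature and each score column on
#'    training statistics;
#' 2. per imaging modality, jointly select regions across the used time
#'    points with the l2,1 model ([gtl_fit()]), the penalty chosen by seeded
#'    inner cross-validation;
#' 3. interpolate each selected region's trajectory
#'    ([extract_poly_features()]) and concatenate raw + coefficient blocks;
#'    the cognitive modality is the plain score vector across time points;
#' 4. unit-norm each subject's per-modality vector, build linear kernels,
#'    pick the kernel weights and cost by seeded inner cross-validation, and
#'    train the multi-kernel SVM.
#'
#' @param train,test `longitudinal_dataset`s with identical modalities and
#'   time points.
#' @param task `"regression"` or `"classification"`.
#' @param target_score score name predicted (regression only).
#' @param target_time time code of the predicted score (regression only;
#'   defaults to the last time point of `train`).
#' @param time_points leading time codes used as input data (default: all
#'   but the target time for regression, all for classification).
#' @param modalities imaging modalities to use (default: all in the data).
#' @param control a [pipeline_control()].
#' @param seed integer; all internal randomness (inner-CV folds) derives from
#'   it, independently of the test data.
#' @return list with `prediction` (numeric vector in original score units for
#'   regression; list with `class` and `decision` for classification) and
#'   `fit`, the training-side record: per-modality `gtl_selection`s, chosen
#'   `lambda`s, kernel weights `beta`, cost `C`, and the normalization
#'   parameters. `fit` is computed from the training data only.
#' @export
proposed_fit_predict <- function(train, test, task = c("regression", "classification"),
                                 target_score = "MMSE", target_time = NULL,
                                 time_points = NULL, modalities = NULL,
                                 control = pipeline_control(), seed = 1L) {
  task <- match.arg(task)
  tt_all <- length(train$time_codes)
  if (is.null(target_time)) target_time <- tt_all
  if (is.null(time_points))
    time_points <- if (task == "regression") seq_len(target_time - 1L)
                   else seq_len(tt_all)
  if (is.null(modalities)) modalities <- train$modalities

  y_tr <- pipeline_target(train, task, target_score, target_time)

  tr <- subset_dataset(train, time_points = time_points)
  te <- subset_dataset(test, time_points = time_points)
  z <- zscore_fit_apply(tr, te)

  feats_tr <- list(); feats_te <- list()
  selections <- list(); lambdas <- numeric(0)
  for (mi in seq_along(modalities)) {
    m <- modalities[mi]
    prob <- selection_problem(z$train, m, task, target_score)
    lam <- control$lambda
    if (is.null(lam)) {
      grid <- gtl_lambda_grid(prob$X, prob$y, n_lambda = control$n_lambda,
                              min_ratio = control$lambda_min_ratio)
      lam <- gtl_select_lambda_cv(prob$X, prob$y, grid = grid,
                                  folds = control$inner_folds,
                                  seed = seed + 101L * mi,
                                  tol = control$tol,
                                  max_iter = control$max_iter)$lambda
    }
    fit <- gtl_fit(prob$X, prob$y, lam, tol = control$tol,
                   max_iter = control$max_iter)
    sel <- fit$selection$selected
    selections[[m]] <- fit$selection
    lambdas[m] <- lam
    feats_tr[[m]] <- modality_feature_matrix(z$train, sel, m, control$use_poly)
    feats_te[[m]] <- modality_feature_matrix(z$test, sel, m, control$use_poly)
  }
  if (control$use_cognitive) {
    feats_tr[["COG"]] <- cognitive_feature_matrix(z$train)
    feats_te[["COG"]] <- cognitive_feature_matrix(z$test)
  }
  feats_tr <- lapply(feats_tr, unit_norm_rows)
  feats_te <- lapply(feats_te, unit_norm_rows)

  # drop zero-width blocks (empty selection): they carry no kernel signal
  widths <- vapply(feats_tr, ncol, integer(1L))
  if (all(widths == 0L)) {
    # nothing selected anywhere: constant predictor
    return(constant_prediction(y_tr, task, n_subjects(te),
                               fit = list(selections = selections,
                                          lambdas = lambdas,
                                          degenerate = TRUE)))
  }
  feats_tr <- feats_tr[widths > 0L]
  feats_te <- feats_te[widths > 0L]

  yz <- svm_targets(y_tr, task)
  gs <- mkl_grid_search(feats_tr, yz$y, task, beta_step = control$beta_step,
                        C_grid = control$C_grid, folds = control$inner_folds,
                        seed = seed + 7919L, epsilon = control$epsilon)
  model <- mkl_train(feats_tr, yz$y, task, beta = gs$beta, C = gs$C,
                     epsilon = control$epsilon)
  pred <- predict(model, feats_te)
  prediction <- if (task == "regression") pred * yz$sd + yz$mean else pred
  list(prediction = prediction,
       fit = list(selections = selections, lambdas = lambdas,
                  beta = stats::setNames(gs$beta, names(feats_tr)),
                  C = gs$C, norm_params = z$params,
                  modalities = names(feats_tr)))
}

# selected raw features across time + polynomial coefficients for a modality
modality_feature_matrix <- function(zds, selected, modality, use_poly = TRUE) {
  if (length(selected) == 0L)
    return(matrix(0, n_subjects(zds), 0L))
  poly <- extract_poly_features(zds, selected, modality)
  mat <- assemble_modality_matrix(zds, poly)
  if (!use_poly) mat <- mat[, seq_len(length(selected) * length(poly$times)),
                            drop = FALSE]
  mat
}

svm_targets <- function(y, task) {
  if (task == "classification") return(list(y = y, mean = 0, sd = 1))
  mu <- mean(y)
  sdv <- max(pop_sd(y), 1e-8)
  list(y = (y - mu) / sdv, mean = mu, sd = sdv)
}

constant_prediction <- function(y_tr, task, n_test, fit) {
  if (task == "regression") {
    list(prediction = rep(mean(y_tr), n_test), fit = fit)
  } else {
    maj <- if (sum(y_tr == 1) > sum(y_tr == -1)) 1 else -1
    list(prediction = list(class = rep(maj, n_test),
                           decision = rep(0, n_test)),
         fit = fit)
  }
}
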