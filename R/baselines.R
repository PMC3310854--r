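#' Majority vote over binary predictions
#'
#' Sign of the vote sum. Ties (possible with an even number of voters) are
#' broken by the sign of the mean decision score when scores are supplied,
#' and toward -1 (non-converter) otherwise.
#'
#' @param votes vector of class votes in `{+1, -1}`.
#' @param scores optional vector of decision scores aligned with `votes`.
#' @return +1 or -1.
#' @export
majority_vote <- function(votes, scores = NULL) {
  if (length(votes) == 0L) stop("no votes", call. = FALSE)
  if (!all(votes %in% c(-1, 1))) stop("votes must be in {+1, -1}", call. = FALSE)
  s <- sum(votes)
  if (s > 0) return(1)
  if (s < 0) return(-1)
  if (!is.null(scores) && mean(scores) > 0) return(1)
  -1
}

# One Lasso + single-kernel SVM block: select columns of Xtr by the T = 1
# group-temporal model (= Lasso) with inner-CV penalty, then train a linear
# SVM on the unit-normed selected columns. Falls back to a constant
# predictor when nothing is selected.
lasso_svm_block <- function(Xtr, ytr, Xte, task, control, seed) {
  Xl <- list(Xtr)
  yl <- list(if (task == "classification") as.numeric(ytr) else ytr)
  lam <- control$lambda
  if (is.null(lam)) {
    grid <- gtl_lambda_grid(Xl, yl, n_lambda = control$n_lambda,
                            min_ratio = control$lambda_min_ratio)
    lam <- gtl_select_lambda_cv(Xl, yl, grid = grid,
                                folds = control$inner_folds, seed = seed,
                                tol = control$tol,
                                max_iter = control$max_iter)$lambda
  }
  fit <- gtl_fit(Xl, yl, lam, tol = control$tol,
                 max_iter = control$max_iter)
  sel <- fit$selection$selected
  if (length(sel) == 0L) {
    cp <- constant_prediction(ytr, task, nrow(Xte),
                              fit = list(selection = fit$selection,
                                         degenerate = TRUE))
    return(list(prediction = cp$prediction, selection = fit$selection,
                lambda = lam, C = NA_real_))
  }
  ftr <- unit_norm_rows(Xtr[, sel, drop = FALSE])
  fte <- unit_norm_rows(Xte[, sel, drop = FALSE])
  yz <- svm_targets(ytr, task)
  gs <- mkl_grid_search(list(block = ftr), yz$y, task, beta_step = 1,
                        C_grid = control$C_grid, folds = control$inner_folds,
                        seed = seed + 13L, epsilon = control$epsilon)
  model <- mkl_train(list(block = ftr), yz$y, task, beta = 1, C = gs$C,
                     epsilon = control$epsilon)
  pred <- predict(model, list(block = fte))
  prediction <- if (task == "regression") pred * yz$sd + yz$mean else pred
  list(prediction = prediction, selection = fit$selection,
       lambda = lam, C = gs$C)
}

# Wide z-scored blocks per (modality, time point), cognitive scores included
# as one block per time point; also returns the concatenation order
# (modality-major, then time, then region).
wide_blocks <- function(zds, use_cognitive = TRUE) {
  blocks <- list()
  for (m in zds$modalities) {
    fm <- zds$features[[m]]
    for (j in seq_len(dim(fm)[2L])) {
      blocks[[paste0(m, "_t", j)]] <-
        matrix(fm[, j, ], dim(fm)[1L],
               dimnames = list(zds$subject_ids,
                               paste0(zds$region_names[[m]], "__t", j)))
    }
  }
  if (use_cognitive) {
    for (j in seq_len(dim(zds$scores)[2L])) {
      blocks[[paste0("COG_t", j)]] <-
        matrix(zds$scores[, j, ], dim(zds$scores)[1L],
               dimnames = list(zds$subject_ids,
                               paste0(zds$score_names, "__t", j)))
    }
  }
  blocks
}

#' CONCAT baseline: concatenate everything, Lasso, single SVM
#'
#' All modalities and time points are concatenated into one long vector per
#' subject (modality-major, then time, then region), a single Lasso (the
#' T = 1 case of the group-temporal model) selects columns against the
#' prediction target, and a standard linear-kernel SVM on the unit-normed
#' selected columns predicts.
#'
#' @inheritParams proposed_fit_predict
#' @return list with `prediction`, and `fit` (selection, lambda, C).
#' @export
concat_fit_predict <- function(train, test, task = c("regression", "classification"),
                               target_score = "MMSE", target_time = NULL,
                               time_points = NULL, control = pipeline_control(),
                               seed = 1L) {
  task <- match.arg(task)
  tt_all <- length(train$time_codes)
  if (is.null(target_time)) target_time <- tt_all
  if (is.null(time_points))
    time_points <- if (task == "regression") seq_len(target_time - 1L)
                   else seq_len(tt_all)
  y_tr <- pipeline_target(train, task, target_score, target_time)
  tr <- subset_dataset(train, time_points = time_points)
  te <- subset_dataset(test, time_points = time_points)
  z <- zscore_fit_apply(tr, te)
  Xtr <- do.call(cbind, wide_blocks(z$train, control$use_cognitive))
  Xte <- do.call(cbind, wide_blocks(z$test, control$use_cognitive))
  res <- lasso_svm_block(Xtr, y_tr, Xte, task, control, seed)
  list(prediction = res$prediction,
       fit = list(selection = res$selection, lambda = res$lambda, C = res$C))
}

#' Ensemble baseline: one Lasso + SVM per (modality, time point)
#'
#' Fits an independent Lasso + linear SVM for each modality at each time
#' point (cognitive scores form one block per time point) and fuses the
#' per-block predictions: majority vote (decision-score tie-break) for
#' classification, unweighted mean for regression.
#'
#' @inheritParams concat_fit_predict
#' @return list with `prediction` and `fit` (per-block lambdas and costs).
#' @export
ensemble_fit_predict <- function(train, test, task = c("regression", "classification"),
                                 target_score = "MMSE", target_time = NULL,
                                 time_points = NULL, control = pipeline_control(),
                                 seed = 1L) {
  task <- match.arg(task)
  tt_all <- length(train$time_codes)
  if (is.null(target_time)) target_time <- tt_all
  if (is.null(time_points))
    time_points <- if (task == "regression") seq_len(target_time - 1L)
                   else seq_len(tt_all)
  y_tr <- pipeline_target(train, task, target_score, target_time)
  tr <- subset_dataset(train, time_points = time_points)
  te <- subset_dataset(test, time_points = time_points)
  z <- zscore_fit_apply(tr, te)
  btr <- wide_blocks(z$train, control$use_cognitive)
  bte <- wide_blocks(z$test, control$use_cognitive)
  preds <- list(); decs <- list(); info <- list()
  for (b in names(btr)) {
    res <- lasso_svm_block(btr[[b]], y_tr, bte[[b]], task, control,
                           seed = seed + 31L * match(b, names(btr)))
    info[[b]] <- list(lambda = res$lambda, C = res$C,
                      n_selected = length(res$selection$selected))
    if (task == "regression") {
      preds[[b]] <- res$prediction
    } else {
      preds[[b]] <- res$prediction$class
      decs[[b]] <- res$prediction$decision
    }
  }
  if (task == "regression") {
    prediction <- Reduce(`+`, preds) / length(preds)
  } else {
    vote_mat <- do.call(cbind, preds)
    dec_mat <- do.call(cbind, decs)
    cls <- vapply(seq_len(nrow(vote_mat)), function(i)
      majority_vote(vote_mat[i, ], dec_mat[i, ]), numeric(1L))
    prediction <- list(class = cls, decision = rowMeans(dec_mat))
  }
  list(prediction = prediction, fit = list(blocks = info))
}

#' Single-modality variants of the proposed method
#'
#' For an imaging modality: the proposed longitudinal selection and feature
#' extraction, followed by a standard (single-kernel) SVM instead of the
#' multi-kernel fusion. For `modality = "COG"`: the concatenated cognitive
#' scores across time points fed straight to an SVM.
#'
#' @inheritParams proposed_fit_predict
#' @param modality one imaging modality name, or `"COG"`.
#' @return list with `prediction` and `fit`.
#' @export
single_modality_fit_predict <- function(train, test,
                                        task = c("regression", "classification"),
                                        modality, target_score = "MMSE",
                                        target_time = NULL, time_points = NULL,
                                        control = pipeline_control(), seed = 1L) {
  task <- match.arg(task)
  if (modality == "COG") {
    ctl <- control
    ctl$use_cognitive <- TRUE
    return(proposed_fit_predict(train, test, task, target_score, target_time,
                                time_points, modalities = character(0),
                                control = ctl, seed = seed))
  }
  ctl <- control
  ctl$use_cognitive <- FALSE
  proposed_fit_predict(train, test, task, target_score, target_time,
                       time_points, modalities = modality, control = ctl,
                       seed = seed)
}
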