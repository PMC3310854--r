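#' Linear kernel between two feature matrices
#'
#' Plain inner products; with unit-normed rows the self-kernel has a unit
#' diagonal (cosine similarity).
#'
#' @param a `N_a x P` matrix.
#' @param b `N_b x P` matrix (default `a`).
#' @return `N_a x N_b` Gram matrix.
#' @export
linear_kernel <- function(a, b = a) {
  if (ncol(a) != ncol(b)) stop("feature dimension mismatch", call. = FALSE)
  tcrossprod(a, b)
}

#' Bundle per-modality Gram matrices
#'
#' Validates symmetry and (approximate) positive semidefiniteness of each
#' kernel.
#'
#' @param kernels named list of `N x N` Gram matrices.
#' @return object of class `kernel_set`.
#' @export
kernel_set <- function(kernels) {
  stopifnot(is.list(kernels), length(kernels) >= 1L, !is.null(names(kernels)))
  n <- nrow(kernels[[1L]])
  for (m in names(kernels)) {
    k <- kernels[[m]]
    if (!is.matrix(k) || nrow(k) != n || ncol(k) != n)
      stop("kernel '", m, "' is not N x N", call. = FALSE)
    if (max(abs(k - t(k))) > 1e-10)
      stop("kernel '", m, "' is not symmetric", call. = FALSE)
    ev <- min(eigen((k + t(k)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop("kernel '", m, "' is not positive semidefinite (min eig ", ev, ")",
           call. = FALSE)
  }
  structure(list(kernels = kernels, modality_names = names(kernels)),
            class = "kernel_set")
}

#' Convex combination of per-modality kernels
#'
#' `K = sum_m beta_m K_m` with `beta` on the probability simplex. Convexity
#' preserves positive semidefiniteness.
#'
#' @param kernels a `kernel_set` or plain named list of Gram matrices.
#' @param beta non-negative weights summing to 1 (one per modality).
#' @return object of class `mixed_kernel`: list with `K` and `beta`.
#' @export
mix_kernels <- function(kernels, beta) {
  if (inherits(kernels, "kernel_set")) kernels <- kernels$kernels
  if (length(beta) != length(kernels))
    stop("one weight per kernel required", call. = FALSE)
  if (any(beta < 0) || abs(sum(beta) - 1) > 1e-9)
    stop("beta must be non-negative and sum to 1", call. = FALSE)
  K <- 0
  for (m in seq_along(kernels)) K <- K + beta[m] * kernels[[m]]
  structure(list(K = K, beta = beta, modality_names = names(kernels)),
            class = "mixed_kernel")
}

#' Enumerate the simplex grid of kernel weights
#'
#' All M-part compositions of 1 in steps of `beta_step` (which must divide 1).
#'
#' @param m number of modalities.
#' @param beta_step grid step (default 0.1).
#' @return matrix with one weight vector per row.
#' @export
simplex_grid <- function(m, beta_step = 0.1) {
  k <- round(1 / beta_step)
  if (abs(k * beta_step - 1) > 1e-9)
    stop("beta_step must divide 1", call. = FALSE)
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- list()
    for (first in 0:total) {
      rest <- compositions(total - first, parts - 1L)
      out[[first + 1L]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  g <- compositions(k, m) / k
  dimnames(g) <- NULL
  g
}

#' Train a multi-kernel SVM on precomputed kernels
#'
#' Builds one linear kernel per modality from unit-normed feature rows, mixes
#' them with the simplex weights `beta`, and hands the mixed Gram matrix to a
#' conventional SVM solver ([kernlab::ksvm()] in precomputed-kernel mode):
#' C-SVC for classification, epsilon-SVR for regression. The model caches the
#' training features so test kernels can be evaluated later; predictions
#' depend on the features only through kernel values.
#'
#' @param features named list of per-modality `N x P_m` matrices (rows
#'   already unit-normed).
#' @param y targets: labels in `{+1, -1}` (classification) or numeric scores
#'   (regression).
#' @param task `"classification"` or `"regression"`.
#' @param beta simplex weights, one per modality.
#' @param C SVM cost parameter.
#' @param epsilon epsilon-tube width for regression (default 0.1).
#' @return object of class `mkl_model`.
#' @export
mkl_train <- function(features, y, task = c("classification", "regression"),
                      beta, C = 1, epsilon = 0.1) {
  task <- match.arg(task)
  stopifnot(is.list(features), length(features) >= 1L)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  kernels <- lapply(features, linear_kernel)
  mk <- mix_kernels(kernels, beta)
  Ktrain <- kernlab::as.kernelMatrix(mk$K)
  if (task == "classification") {
    if (!all(y %in% c(-1, 1)))
      stop("classification labels must be in {+1, -1}", call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("degenerate training set: a single class", call. = FALSE)
    yf <- factor(y, levels = c(-1, 1))
    svm <- kernlab::ksvm(Ktrain, yf, type = "C-svc", C = C, tol = 1e-6,
                         shrinking = FALSE)
    # orient decision scores so that positive score => class +1
    dec_tr <- as.numeric(kernlab::predict(
      svm, kernlab::as.kernelMatrix(mk$K[, kernlab::SVindex(svm), drop = FALSE]),
      type = "decision"))
    cls_tr <- as.numeric(as.character(kernlab::predict(
      svm, kernlab::as.kernelMatrix(mk$K[, kernlab::SVindex(svm), drop = FALSE]))))
    flip <- orient_decision(dec_tr, cls_tr)
  } else {
    svm <- kernlab::ksvm(Ktrain, as.numeric(y), type = "eps-svr", C = C,
                         epsilon = epsilon, tol = 1e-6, shrinking = FALSE)
    flip <- 1
  }
  structure(list(task = task, beta = mk$beta, C = C,
                 epsilon = if (task == "regression") epsilon else NULL,
                 svm = svm, flip = flip,
                 train_features = features,
                 modality_names = names(features)),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("mkl_model (", x$task, "): beta = (",
      paste(signif(x$beta, 3), collapse = ", "), "), C = ", x$C, "\n", sep = "")
  invisible(x)
}

#' Predict from a multi-kernel SVM
#'
#' Computes each modality's test-vs-training linear kernel, mixes with the
#' training weights, and evaluates the wrapped solver.
#'
#' @param object an `mkl_model`.
#' @param newfeatures named list of per-modality test matrices, processed
#'   exactly as the training features (same normalization, unit norm).
#' @param ... unused.
#' @return for regression, numeric predictions; for classification, a list
#'   with `class` (+1/-1) and `decision` (signed scores, positive = +1).
#' @export
predict.mkl_model <- function(object, newfeatures, ...) {
  if (!identical(names(newfeatures), object$modality_names))
    stop("modalities of newfeatures do not match the training set",
         call. = FALSE)
  Kcross <- 0
  for (m in seq_along(newfeatures)) {
    if (ncol(newfeatures[[m]]) != ncol(object$train_features[[m]]))
      stop("feature dimension mismatch for modality ",
           object$modality_names[m], call. = FALSE)
    Kcross <- Kcross + object$beta[m] *
      linear_kernel(newfeatures[[m]], object$train_features[[m]])
  }
  sv <- kernlab::SVindex(object$svm)
  Ktest <- kernlab::as.kernelMatrix(Kcross[, sv, drop = FALSE])
  if (object$task == "regression")
    return(as.numeric(kernlab::predict(object$svm, Ktest)))
  decision <- object$flip * as.numeric(kernlab::predict(object$svm, Ktest,
                                                        type = "decision"))
  list(class = ifelse(decision >= 0, 1, -1), decision = decision)
}

#' Grid search over kernel weights and SVM cost
#'
#' Enumerates the full simplex grid of kernel weights and a cost grid, and
#' scores every combination by seeded inner cross-validation on the training
#' features: accuracy (maximized) for classification, RMSE (minimized) for
#' regression. Ties are broken toward the more uniform weight vector (smaller
#' sum of squared weights), then toward the smaller C.
#'
#' @inheritParams mkl_train
#' @param beta_step simplex grid step (must divide 1).
#' @param C_grid candidate costs (default `2^seq(-5, 5, 2)`).
#' @param folds inner folds.
#' @param seed fold-assignment seed.
#' @return list with `beta`, `C`, and `cv_table` (one row per combination).
#' @export
mkl_grid_search <- function(features, y, task = c("classification", "regression"),
                            beta_step = 0.1, C_grid = 2^seq(-5, 5, 2),
                            folds = 5L, seed = 1L, epsilon = 0.1) {
  task <- match.arg(task)
  if (length(C_grid) == 0L) stop("empty C grid", call. = FALSE)
  m <- length(features)
  betas <- simplex_grid(m, beta_step)
  n <- nrow(features[[1L]])
  strat <- if (task == "classification") y else NULL
  fold_id <- make_folds(n, min(folds, n), labels = strat, seed = seed)
  kernels <- lapply(features, linear_kernel)

  n_comb <- nrow(betas) * length(C_grid)
  tab <- data.frame(beta = character(n_comb), C = numeric(n_comb),
                    score = numeric(n_comb))
  best <- NULL
  row <- 0L
  for (bi in seq_len(nrow(betas))) {
    beta <- betas[bi, ]
    Kmix <- mix_kernels(kernels, beta)$K
    for (C in C_grid) {
      row <- row + 1L
      vals <- numeric(max(fold_id))
      ok <- TRUE
      for (f in seq_len(max(fold_id))) {
        tr <- fold_id != f
        if (task == "classification" && length(unique(y[tr])) < 2L) {
          ok <- FALSE; break
        }
        fit <- tryCatch(
          svm_on_kernel(Kmix[tr, tr, drop = FALSE], y[tr], task, C, epsilon),
          error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        pred <- svm_kernel_predict(fit, Kmix[!tr, tr, drop = FALSE])
        vals[f] <- if (task == "classification")
          mean(pred$class == y[!tr]) else sqrt(mean((pred - y[!tr])^2))
      }
      score <- if (!ok) NA_real_ else mean(vals)
      tab$beta[row] <- paste(signif(beta, 6), collapse = "/")
      tab$C[row] <- C
      tab$score[row] <- score
      if (is.na(score)) next
      cand <- list(beta = beta, C = C, score = score,
                   spread = sum(beta^2))
      if (is.null(best) || better_combo(cand, best, task)) best <- cand
    }
  }
  if (is.null(best)) stop("no grid combination could be evaluated", call. = FALSE)
  list(beta = best$beta, C = best$C, cv_table = tab)
}

better_combo <- function(a, b, task) {
  eps <- 1e-12
  gain <- if (task == "classification") a$score - b$score else b$score - a$score
  if (gain > eps) return(TRUE)
  if (gain < -eps) return(FALSE)
  if (a$spread < b$spread - eps) return(TRUE)
  if (a$spread > b$spread + eps) return(FALSE)
  a$C < b$C
}

# bare solver wrappers on a precomputed (sub)kernel, used by the grid search
svm_on_kernel <- function(K, y, task, C, epsilon = 0.1) {
  Km <- kernlab::as.kernelMatrix(K)
  if (task == "classification") {
    yf <- factor(y, levels = c(-1, 1))
    svm <- kernlab::ksvm(Km, yf, type = "C-svc", C = C, tol = 1e-6,
                         shrinking = FALSE)
    dec <- as.numeric(kernlab::predict(
      svm, kernlab::as.kernelMatrix(K[, kernlab::SVindex(svm), drop = FALSE]),
      type = "decision"))
    cls <- as.numeric(as.character(kernlab::predict(
      svm, kernlab::as.kernelMatrix(K[, kernlab::SVindex(svm), drop = FALSE]))))
    list(svm = svm, task = task, flip = orient_decision(dec, cls))
  } else {
    list(svm = kernlab::ksvm(Km, as.numeric(y), type = "eps-svr", C = C,
                             epsilon = epsilon, tol = 1e-6, shrinking = FALSE),
         task = task, flip = 1)
  }
}

# kernlab's decision-value sign depends on internal label ordering; orient it
# so that a positive score means class +1, by majority agreement with the
# solver's own training-set class predictions.
orient_decision <- function(dec, cls) {
  agree_pos <- sum(ifelse(dec >= 0, 1, -1) == cls)
  agree_neg <- sum(ifelse(dec >= 0, -1, 1) == cls)
  if (agree_pos >= agree_neg) 1 else -1
}

svm_kernel_predict <- function(fit, Kcross) {
  sv <- kernlab::SVindex(fit$svm)
  Kt <- kernlab::as.kernelMatrix(Kcross[, sv, drop = FALSE])
  if (fit$task == "regression")
    return(as.numeric(kernlab::predict(fit$svm, Kt)))
  decision <- fit$flip * as.numeric(kernlab::predict(fit$svm, Kt,
                                                     type = "decision"))
  list(class = ifelse(decision >= 0, 1, -1), decision = decision)
}
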