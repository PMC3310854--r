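test_that("objective matches a naive loop-based recomputation", {
  for (s in 1:5) {
    inst <- random_gtl_instance(n = 12L, d = 6L, tt = 3L, seed = s)
    set.seed(100 + s)
    W <- matrix(rnorm(6 * 3), 6, 3)
    lam <- runif(1, 0, 5)
    naive <- 0
    for (j in 1:3) {
      for (i in 1:12) {
        pred <- 0
        for (k in 1:6) pred <- pred + inst$X[[j]][i, k] * W[k, j]
        naive <- naive + (inst$y[[j]][i] - pred)^2
      }
    }
    for (k in 1:6) naive <- naive + lam * sqrt(sum(W[k, ]^2))
    expect_equal(gtl_objective(W, inst$X, inst$y, lam), naive,
                 tolerance = 1e-12)
  }
  # zero model leaves only the target energy
  inst <- random_gtl_instance(seed = 9)
  expect_equal(gtl_objective(matrix(0, 10, 3), inst$X, inst$y, 2.5),
               sum(vapply(inst$y, function(v) sum(v^2), numeric(1L))))
})

test_that("prox_l21 block soft-thresholds rows", {
  expect_equal(prox_l21(matrix(c(3, 4), 1), 2.5), matrix(c(1.5, 2.0), 1))
  # any row with norm <= tau collapses to zero
  V <- rbind(c(0.3, 0.4), c(3, 4), c(0, 0))
  out <- prox_l21(V, 0.5)
  expect_equal(out[1, ], c(0, 0))
  expect_equal(out[3, ], c(0, 0))
  expect_true(all(out[2, ] != 0))
  # tau = 0 is the identity
  expect_identical(prox_l21(V, 0), V)
})

test_that("with one time point the fit matches a coordinate-descent Lasso", {
  for (s in 1:5) {
    inst <- random_gtl_instance(n = 30L, d = 10L, tt = 1L, seed = 20 + s,
                                sparse_truth = TRUE)
    lam <- gtl_lambda_max(inst$X, inst$y) / c(5, 20, 60)[(s %% 3) + 1]
    w_cd <- cd_lasso(inst$X[[1L]], inst$y[[1L]], lam)
    fit <- gtl_fit(inst$X, inst$y, lam, tol = 1e-13, max_iter = 30000L,
                   center_y = FALSE)
    expect_lt(max(abs(w_cd - fit$W[, 1L])), 1e-5)
  }
})

test_that("with no penalty each column is the per-time-point least-squares fit", {
  inst <- random_gtl_instance(n = 25L, d = 8L, tt = 2L, seed = 31L,
                              sparse_truth = TRUE)
  fit <- gtl_fit(inst$X, inst$y, 0, tol = 1e-14, max_iter = 50000L,
                 center_y = FALSE)
  for (j in 1:2) {
    ols <- solve(crossprod(inst$X[[j]]), crossprod(inst$X[[j]], inst$y[[j]]))
    expect_equal(fit$W[, j], as.numeric(ols), tolerance = 1e-5)
  }
})

test_that("lambda_max is the exact zero-solution threshold", {
  for (s in 1:10) {
    inst <- random_gtl_instance(seed = 40 + s, sparse_truth = TRUE)
    lmax <- gtl_lambda_max(inst$X, inst$y)
    fit <- gtl_fit(inst$X, inst$y, lmax, center_y = FALSE)
    expect_true(all(fit$W == 0))
    fit_half <- gtl_fit(inst$X, inst$y, lmax / 2, center_y = FALSE)
    expect_gte(length(fit_half$selection$selected), 1L)
  }
  # zero targets give zero threshold
  inst <- random_gtl_instance(seed = 50)
  y0 <- lapply(inst$y, function(v) v * 0)
  expect_equal(gtl_lambda_max(inst$X, y0), 0)
  # T = 1 reduces to the classical 2 * ||X'y||_inf
  inst1 <- random_gtl_instance(tt = 1L, seed = 51)
  expect_equal(gtl_lambda_max(inst1$X, inst1$y),
               2 * max(abs(crossprod(inst1$X[[1L]], inst1$y[[1L]]))),
               tolerance = 1e-12)
})

test_that("the objective is non-increasing along the iterations", {
  for (s in 1:5) {
    inst <- random_gtl_instance(seed = 60 + s, sparse_truth = TRUE)
    lam <- gtl_lambda_max(inst$X, inst$y) / 10
    fit <- gtl_fit(inst$X, inst$y, lam, tol = 1e-12, max_iter = 2000L)
    tr <- fit$selection$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * max(abs(tr))))
  }
})

test_that("rows are selected jointly: per-column supports agree", {
  for (s in 1:5) {
    inst <- random_gtl_instance(seed = 70 + s, sparse_truth = TRUE)
    lam <- gtl_lambda_max(inst$X, inst$y) / 8
    fit <- gtl_fit(inst$X, inst$y, lam, center_y = FALSE)
    sel_rows <- fit$selection$selected
    for (j in seq_len(ncol(fit$W))) {
      col_support <- which(abs(fit$W[, j]) > 0)
      # every nonzero entry lives in a selected row, and every selected row
      # is nonzero as a row
      expect_true(all(col_support %in% sel_rows))
    }
    expect_true(all(sqrt(rowSums(fit$W[sel_rows, , drop = FALSE]^2)) > 1e-8))
  }
})

test_that("scaling targets and penalty by c scales the solution by c", {
  inst <- random_gtl_instance(seed = 81, sparse_truth = TRUE)
  lam <- gtl_lambda_max(inst$X, inst$y) / 10
  f1 <- gtl_fit(inst$X, inst$y, lam, tol = 1e-13, max_iter = 30000L,
                center_y = FALSE)
  cc <- 3.7
  y2 <- lapply(inst$y, function(v) cc * v)
  f2 <- gtl_fit(inst$X, y2, cc * lam, tol = 1e-13, max_iter = 30000L,
                center_y = FALSE)
  expect_equal(f2$W, cc * f1$W, tolerance = 1e-6)
})

test_that("a singleton grid is returned as-is and tiny pools error", {
  inst <- random_gtl_instance(n = 20L, seed = 90)
  res <- gtl_select_lambda_cv(inst$X, inst$y, grid = 0.7, folds = 4L)
  expect_equal(res$lambda, 0.7)
  expect_error(gtl_select_lambda_cv(inst$X, inst$y, folds = 30L), "folds")
})

test_that("pure-noise targets drive the cross-validated penalty to the grid top", {
  hits <- vapply(1:20, function(s) {
    inst <- random_gtl_instance(n = 40L, d = 15L, tt = 3L, seed = 200 + s)
    res <- gtl_select_lambda_cv(inst$X, inst$y, folds = 5L, seed = s)
    res$lambda == max(res$grid)
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})

test_that("near-noiseless signal recovers exactly the score-driving support", {
  hits <- vapply(1:20, function(s) {
    ch <- quick_cohort(seed = 300 + s, noise = 1e-3,
                       score_noise_sd = 1e-3, subject_sd = 1,
                       modalities = "MRI")
    zds <- zscore_fit_apply(ch$dataset)$train
    prob <- selection_problem(zds, "MRI", "regression", "MMSE")
    res <- gtl_select_lambda_cv(prob$X, prob$y, folds = 5L, seed = s)
    fit <- gtl_fit(prob$X, prob$y, res$lambda)
    truth <- sort(ch$truth$score_model$MMSE$regions$MRI)
    identical(sort(fit$selection$selected), truth)
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})
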