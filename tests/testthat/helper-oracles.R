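# Independent reference implementations used only to check the package's
# own solvers and metrics. Deliberately simple and slow.

# Coordinate-descent Lasso for  min ||y - X w||^2 + lambda * ||w||_1
# (same loss convention as gtl_objective with T = 1).
cd_lasso <- function(X, y, lambda, max_iter = 10000L, tol = 1e-12) {
  d <- ncol(X)
  w <- rep(0, d)
  xsq <- colSums(X^2)
  r <- y
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(d)) {
      if (xsq[k] == 0) next
      zk <- sum(X[, k] * r) + xsq[k] * w[k]
      wk <- soft(zk, lambda / 2) / xsq[k]
      if (wk != w[k]) {
        r <- r - X[, k] * (wk - w[k])
        delta <- max(delta, abs(wk - w[k]))
        w[k] <- wk
      }
    }
    if (delta < tol) break
  }
  w
}

# Projected-gradient oracle for the full l2,1 problem, on the smooth epigraph
# reformulation: minimize  sum_j ||y_j - X_j w_j||^2 + lambda * sum_d r_d
# subject to ||W_d.|| <= r_d, by constant-step projected gradient with
# per-row second-order-cone projection. Independent of the FISTA path.
soc_pg_oracle <- function(X, y, lambda, iters = 50000L) {
  d <- ncol(X[[1L]])
  tt <- length(X)
  XtX <- lapply(X, crossprod)
  Xty <- lapply(seq_len(tt), function(j) crossprod(X[[j]], y[[j]]))
  L <- 2 * max(vapply(XtX, function(a) max(eigen(a, symmetric = TRUE,
                                                 only.values = TRUE)$values),
                      numeric(1L)))
  W <- matrix(0, d, tt)
  r <- rep(0, d)
  step <- 1 / L
  for (it in seq_len(iters)) {
    G <- matrix(0, d, tt)
    for (j in seq_len(tt)) G[, j] <- 2 * (XtX[[j]] %*% W[, j] - Xty[[j]])
    W <- W - step * G
    r <- r - step * lambda
    # project each (W_d., r_d) onto the second-order cone ||w|| <= s
    nrm <- sqrt(rowSums(W^2))
    inside <- nrm <= r
    polar <- nrm <= -r
    boundary <- !(inside | polar)
    if (any(polar)) { W[polar, ] <- 0; r[polar] <- 0 }
    if (any(boundary)) {
      a <- (nrm[boundary] + r[boundary]) / 2
      W[boundary, ] <- W[boundary, ] * (a / nrm[boundary])
      r[boundary] <- a
    }
  }
  W
}

# Brute-force metric re-implementations.
bf_corr <- function(y, yhat) {
  cy <- y - mean(y); ch <- yhat - mean(yhat)
  sum(cy * ch) / sqrt(sum(cy^2) * sum(ch^2))
}

bf_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

bf_confusion <- function(labels, preds) {
  tp <- sum(labels == 1 & preds == 1); fn <- sum(labels == 1 & preds == -1)
  tn <- sum(labels == -1 & preds == -1); fp <- sum(labels == -1 & preds == 1)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Small random per-time-point regression instances.
random_gtl_instance <- function(n = 30L, d = 10L, tt = 3L, seed = 1L,
                                sparse_truth = FALSE) {
  set.seed(seed)
  X <- lapply(seq_len(tt), function(j) matrix(rnorm(n * d), n, d))
  if (sparse_truth) {
    w <- matrix(0, d, tt)
    w[seq_len(max(1L, d %/% 3L)), ] <- rnorm(max(1L, d %/% 3L) * tt, sd = 2)
    y <- lapply(seq_len(tt), function(j) X[[j]] %*% w[, j] + rnorm(n, sd = 0.3))
    y <- lapply(y, as.numeric)
  } else {
    y <- lapply(seq_len(tt), function(j) rnorm(n))
  }
  list(X = X, y = y)
}

# Small quick cohorts for pipeline-level tests.
quick_cohort <- function(seed = 1L, n = 40L, conv = 18L, d = 15L,
                         informative = 4L, noise = 0.6, ...) {
  generate_cohort(synthetic_config(
    n_subjects = n, n_converters = conv, n_regions = d,
    n_informative = informative, overlap = informative %/% 2L,
    noise_sd = noise, seed = seed, ...))
}

# Fast pipeline control for tests.
quick_control <- function(...) {
  pipeline_control(n_lambda = 8L, inner_folds = 3L, beta_step = 0.5,
                   C_grid = c(0.5, 4, 32), ...)
}
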