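#' Construct a longitudinal multimodal dataset
#'
#' The central container of the package: `N` subjects measured on `M`
#' modalities (e.g. regional MRI volumes, regional PET intensities) over `T`
#' ordered time points, together with per-time-point clinical scores (e.g.
#' MMSE, ADAS-Cog) and an optional binary converter label per subject.
#'
#' Time points are coded as the integers `1..T`; calendar labels such as
#' `"bl"`, `"M06"` are metadata only and never enter any computation.
#' Missing visits are supported only as trailing truncation via `subject_T`
#' (a subject observed for its first `subject_T[i]` time points); interior
#' gaps are rejected.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param features named list, one element per modality, each an
#'   `N x T x D_m` numeric array with dimnames `(subject, time, region)`.
#' @param scores `N x T x S` numeric array of clinical scores, dimnames
#'   `(subject, time, score)`.
#' @param labels optional named numeric vector in `{+1, -1}` (+1 = converter).
#' @param time_labels optional character labels for the `T` time codes
#'   (default `"bl", "M06", "M12", ...`).
#' @param subject_T optional integer vector: number of usable leading time
#'   points per subject (defaults to `T` for everyone).
#'
#' @return An object of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(subject_ids, features, scores, labels = NULL,
                                 time_labels = NULL, subject_T = NULL) {
  stopifnot(is.list(features), length(features) >= 1L, !is.null(names(features)))
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  tt <- dim(features[[1L]])[2L]
  for (m in names(features)) {
    fm <- features[[m]]
    if (!is.array(fm) || length(dim(fm)) != 3L)
      stop("features[['", m, "']] must be an N x T x D array", call. = FALSE)
    if (dim(fm)[1L] != n || dim(fm)[2L] != tt)
      stop("features[['", m, "']] dimensions inconsistent with subjects/times",
           call. = FALSE)
  }
  if (!is.array(scores) || length(dim(scores)) != 3L ||
      dim(scores)[1L] != n || dim(scores)[2L] != tt)
    stop("scores must be an N x T x S array consistent with features",
         call. = FALSE)
  if (is.null(time_labels)) time_labels <- default_time_labels(tt)
  stopifnot(length(time_labels) == tt)
  if (is.null(subject_T)) subject_T <- rep.int(tt, n)
  subject_T <- as.integer(subject_T)
  stopifnot(length(subject_T) == n, all(subject_T >= 1L), all(subject_T <= tt))
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    stopifnot(length(labels) == n)
    if (!all(labels %in% c(-1, 1)))
      stop("labels must take exactly the values {+1, -1}", call. = FALSE)
    names(labels) <- subject_ids
  }
  for (m in names(features)) {
    for (i in seq_len(n)) {
      v <- features[[m]][i, seq_len(subject_T[i]), , drop = FALSE]
      if (anyNA(v))
        stop("missing feature values within subject_T horizon for subject ",
             subject_ids[i], call. = FALSE)
    }
  }
  structure(
    list(subject_ids = as.character(subject_ids),
         modalities = names(features),
         time_codes = seq_len(tt),
         time_labels = time_labels,
         features = features,
         region_names = lapply(features, function(f) dimnames(f)[[3L]]),
         scores = scores,
         score_names = dimnames(scores)[[3L]],
         labels = labels,
         subject_T = subject_T),
    class = "longitudinal_dataset")
}

default_time_labels <- function(tt) {
  c("bl", sprintf("M%02d", 6L * seq_len(max(tt - 1L, 0L))))[seq_len(tt)]
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat("longitudinal_dataset:", length(x$subject_ids), "subjects,",
      length(x$time_codes), "time points (", paste(x$time_labels, collapse = ", "),
      ")\n")
  for (m in x$modalities)
    cat("  modality", m, ":", dim(x$features[[m]])[3L], "regions\n")
  cat("  scores:", paste(x$score_names, collapse = ", "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", sum(x$labels == 1), "converters /",
        sum(x$labels == -1), "non-converters\n")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param x a `longitudinal_dataset`.
#' @return integer subject count.
#' @export
n_subjects <- function(x) length(x$subject_ids)

#' Subset a dataset by subjects and/or leading time points
#'
#' @param x a `longitudinal_dataset`.
#' @param subjects integer or logical index of subjects to keep.
#' @param time_points integer vector of time codes to keep; must be a prefix
#'   `1..T'` of the existing codes (trajectory features assume consecutive
#'   visits from baseline).
#' @return a `longitudinal_dataset`.
#' @export
subset_dataset <- function(x, subjects = NULL, time_points = NULL) {
  idx <- if (is.null(subjects)) seq_along(x$subject_ids) else subjects
  if (is.logical(idx)) idx <- which(idx)
  tp <- if (is.null(time_points)) x$time_codes else as.integer(time_points)
  if (!identical(tp, seq_len(length(tp))))
    stop("time_points must be the leading codes 1..T'", call. = FALSE)
  feats <- lapply(x$features, function(f) f[idx, tp, , drop = FALSE])
  longitudinal_dataset(
    subject_ids = x$subject_ids[idx],
    features = feats,
    scores = x$scores[idx, tp, , drop = FALSE],
    labels = if (!is.null(x$labels)) x$labels[idx],
    time_labels = x$time_labels[tp],
    subject_T = pmin(x$subject_T[idx], length(tp)))
}

#' Read a long-format cohort from disk
#'
#' Reads the canonical on-disk representation: a tidy features table with
#' columns `subject_id, modality, time_code, region, value` and a companion
#' targets table with columns `subject_id, time_code, score_name, value`
#' and optionally `label` (+1/-1 per subject, constant across rows).
#'
#' Ordering is deterministic: subjects sorted by id, regions by name, time
#' codes ascending.
#'
#' @param features_path path to the features CSV/TSV (separator sniffed by
#'   [data.table::fread()]).
#' @param targets_path path to the targets CSV/TSV.
#' @return a `longitudinal_dataset`.
#' @export
read_long_table <- function(features_path, targets_path) {
  ft <- data.table::fread(features_path)
  needed <- c("subject_id", "modality", "time_code", "region", "value")
  if (!all(needed %in% names(ft)))
    stop("features table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  tg <- data.table::fread(targets_path)
  needed_t <- c("subject_id", "time_code", "score_name", "value")
  if (!all(needed_t %in% names(tg)))
    stop("targets table must have columns: ", paste(needed_t, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ft[, c("subject_id", "modality", "time_code", "region")]))
    stop("duplicate (subject, modality, time, region) records", call. = FALSE)

  subjects <- sort(unique(ft$subject_id))
  # time codes may extend beyond the last observed feature visit (e.g. a
  # prediction-target score at a later visit), so pool both tables
  tcodes <- sort(unique(c(ft$time_code, tg$time_code)))
  if (!identical(as.integer(tcodes), seq_along(tcodes)))
    stop("time codes must be the integers 1..T", call. = FALSE)
  tt <- length(tcodes)
  modalities <- sort(unique(ft$modality))

  features <- list()
  subject_T <- rep.int(tt, length(subjects))
  for (m in modalities) {
    fm <- ft[ft$modality == m, ]
    regions <- sort(unique(fm$region))
    arr <- array(NA_real_, dim = c(length(subjects), tt, length(regions)),
                 dimnames = list(subjects, NULL, regions))
    arr[cbind(match(fm$subject_id, subjects), fm$time_code,
              match(fm$region, regions))] <- fm$value
    # presence pattern per (subject, time): all regions or none
    complete <- apply(!is.na(arr), c(1L, 2L), all)
    partial <- apply(is.na(arr), c(1L, 2L), any) & apply(!is.na(arr), c(1L, 2L), any)
    if (any(partial))
      stop("ragged data: region sets differ across subjects within modality ", m,
           call. = FALSE)
    for (i in seq_along(subjects)) {
      obs <- which(complete[i, ])
      if (length(obs) == 0L)
        stop("subject ", subjects[i], " has no data for modality ", m,
             call. = FALSE)
      if (!identical(obs, seq_len(max(obs))))
        stop("interior time gap for subject ", subjects[i], " in modality ", m,
             call. = FALSE)
      subject_T[i] <- min(subject_T[i], max(obs))
    }
    features[[m]] <- arr
  }

  score_names <- sort(unique(tg$score_name))
  sc <- array(NA_real_, dim = c(length(subjects), tt, length(score_names)),
              dimnames = list(subjects, NULL, score_names))
  sc[cbind(match(tg$subject_id, subjects), tg$time_code,
           match(tg$score_name, score_names))] <- tg$value
  labels <- NULL
  if ("label" %in% names(tg)) {
    lab <- unique(tg[, c("subject_id", "label")])
    if (anyDuplicated(lab$subject_id))
      stop("inconsistent labels across rows for some subject", call. = FALSE)
    labels <- lab$label[match(subjects, lab$subject_id)]
  }
  longitudinal_dataset(subjects, features, sc, labels = labels,
                       subject_T = subject_T)
}

#' Write a cohort to the canonical long format
#'
#' Inverse of [read_long_table()]: emits the tidy features table and the
#' targets table. Rows beyond a subject's `subject_T` horizon are omitted
#' for features; scores are written wherever non-missing.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param features_path,targets_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_long_table <- function(dataset, features_path, targets_path) {
  rows <- list()
  for (m in dataset$modalities) {
    fm <- dataset$features[[m]]
    regions <- dataset$region_names[[m]]
    for (j in dataset$time_codes) {
      keep <- dataset$subject_T >= j
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.table::data.table(
        subject_id = rep(dataset$subject_ids[keep], times = length(regions)),
        modality = m, time_code = j,
        region = rep(regions, each = sum(keep)),
        value = as.vector(fm[keep, j, ]))
    }
  }
  ft <- data.table::rbindlist(rows)
  data.table::setorder(ft, subject_id, modality, time_code, region)
  data.table::fwrite(ft, features_path)

  srows <- list()
  for (s in seq_along(dataset$score_names)) {
    for (j in dataset$time_codes) {
      v <- dataset$scores[, j, s]
      keep <- !is.na(v)
      if (!any(keep)) next
      srows[[length(srows) + 1L]] <- data.table::data.table(
        subject_id = dataset$subject_ids[keep], time_code = j,
        score_name = dataset$score_names[s], value = v[keep])
    }
  }
  tg <- data.table::rbindlist(srows)
  if (!is.null(dataset$labels))
    tg$label <- dataset$labels[match(tg$subject_id, dataset$subject_ids)]
  data.table::setorder(tg, subject_id, time_code, score_name)
  data.table::fwrite(tg, targets_path)
  invisible(c(features_path, targets_path))
}

#' Z-score features on training statistics
#'
#' Standardizes every (modality, time, region) feature column by subtracting
#' the training mean and dividing by the training population standard
#' deviation (1/N convention), then applies the same transform to the test
#' set. Statistics come from the training subjects only. Constant columns
#' get their standard deviation floored at `1e-8` (with a warning), so they
#' map to zero rather than NaN.
#'
#' @param train a `longitudinal_dataset` (statistics fitted here).
#' @param test optional `longitudinal_dataset` transformed with the training
#'   statistics.
#' @param include_scores also standardize the clinical-score array (used when
#'   scores act as a feature modality). Default `TRUE`.
#' @return list with elements `train`, `test` (or `NULL`) and `params`, a
#'   `normalization_params` object holding the per-column means and sds.
#' @export
zscore_fit_apply <- function(train, test = NULL, include_scores = TRUE) {
  sd_floor <- 1e-8
  params <- list(fitted_on = train$subject_ids, sd_floor = sd_floor,
                 feature_stats = list(), score_stats = NULL)
  n_floored <- 0L
  tr <- train
  te <- test
  for (m in train$modalities) {
    fm <- train$features[[m]]
    dm <- dim(fm)
    mu <- apply(fm, c(2L, 3L), mean)
    sdv <- apply(fm, c(2L, 3L), pop_sd)
    n_floored <- n_floored + sum(sdv < sd_floor)
    sdv <- pmax(sdv, sd_floor)
    params$feature_stats[[m]] <- list(mean = mu, sd = sdv)
    tr$features[[m]] <- scale_array(tr$features[[m]], mu, sdv)
    if (!is.null(te)) te$features[[m]] <- scale_array(te$features[[m]], mu, sdv)
  }
  if (include_scores) {
    mu <- apply(train$scores, c(2L, 3L), mean)
    sdv <- apply(train$scores, c(2L, 3L), pop_sd)
    n_floored <- n_floored + sum(sdv < sd_floor, na.rm = TRUE)
    sdv <- pmax(sdv, sd_floor)
    params$score_stats <- list(mean = mu, sd = sdv)
    tr$scores <- scale_array(tr$scores, mu, sdv)
    if (!is.null(te)) te$scores <- scale_array(te$scores, mu, sdv)
  }
  if (n_floored > 0L)
    warning(n_floored, " constant feature column(s): sd floored at ", sd_floor)
  structure_params <- structure(params, class = "normalization_params")
  list(train = tr, test = te, params = structure_params)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

scale_array <- function(arr, mu, sdv) {
  n <- dim(arr)[1L]
  out <- arr
  for (k in seq_len(dim(arr)[3L]))
    out[, , k] <- (arr[, , k] - matrix(mu[, k], n, dim(arr)[2L], byrow = TRUE)) /
      matrix(sdv[, k], n, dim(arr)[2L], byrow = TRUE)
  out
}

#' @export
print.normalization_params <- function(x, ...) {
  cat("normalization_params fitted on", length(x$fitted_on), "subjects;",
      length(x$feature_stats), "modalities\n")
  invisible(x)
}

#' Scale a vector to unit Euclidean norm
#'
#' All-zero vectors are returned unchanged with a warning (there is no unit
#' vector in their direction).
#'
#' @param v numeric vector.
#' @return numeric vector with `sum(v^2) == 1`, or `v` if all-zero.
#' @export
unit_norm <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    warning("all-zero vector left unchanged by unit_norm")
    return(v)
  }
  v / nrm
}

# Row-wise unit norming of a feature matrix (zero rows left, no warning spam).
unit_norm_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}
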