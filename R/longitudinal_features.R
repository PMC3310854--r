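#' Exact polynomial coefficients of one trajectory
#'
#' Fits the unique degree-(T-1) polynomial `u(t) = c_0 + c_1 t + ... +
#' c_{T-1} t^{T-1}` through the T observed values at the integer time codes
#' `t = 1..T`, by solving the T x T Vandermonde system. With T points and T
#' coefficients the fit is an exact interpolation; the coefficients summarize
#' the trajectory (c_1 generalizes the two-point "thinning speed" slope).
#'
#' The monomial basis on `1..T` is well-conditioned for the T <= 5 visits of
#' the intended setting; a conditioning warning is issued beyond T = 8.
#'
#' @param values numeric vector of T observed values.
#' @param times time codes (default `1..T`); must be distinct.
#' @return numeric vector `(c_0, ..., c_{T-1})`.
#' @export
fit_poly_coeffs <- function(values, times = seq_along(values)) {
  tt <- length(values)
  if (length(times) != tt) stop("values and times lengths differ", call. = FALSE)
  if (anyDuplicated(times)) stop("duplicate time codes: singular system",
                                 call. = FALSE)
  if (tt > 8L)
    warning("Vandermonde interpolation beyond T = 8 is ill-conditioned")
  if (tt == 1L) return(as.numeric(values))
  V <- outer(as.numeric(times), 0:(tt - 1L), `^`)
  as.numeric(solve(V, values))
}

#' Polynomial longitudinal features for all subjects and selected regions
#'
#' Applies [fit_poly_coeffs()] to every (subject, selected region) trajectory
#' of one modality, yielding an `N x D_sel x T` coefficient array: the new
#' longitudinal features.
#'
#' @param dataset a `longitudinal_dataset` (all subjects must carry the full
#'   `T` time points being used).
#' @param selected integer indices of selected regions within the modality.
#' @param modality modality name.
#' @return object of class `poly_features`: list with `coeffs`
#'   (`N x D_sel x T`), `times`, `modality`, `selected`.
#' @export
extract_poly_features <- function(dataset, selected, modality) {
  if (!modality %in% dataset$modalities)
    stop("unknown modality: ", modality, call. = FALSE)
  fm <- dataset$features[[modality]]
  tt <- dim(fm)[2L]
  if (length(selected) == 0L) {
    warning("empty selection: returning empty longitudinal feature block")
    coeffs <- array(0, dim = c(dim(fm)[1L], 0L, tt))
  } else {
    # one Vandermonde solve for all trajectories at once:
    # coeffs = V^{-1} %*% values, batched over (subject, region)
    V <- outer(seq_len(tt), 0:(tt - 1L), `^`)
    n <- dim(fm)[1L]
    coeffs <- array(0, dim = c(n, length(selected), tt),
                    dimnames = list(dataset$subject_ids,
                                    dataset$region_names[[modality]][selected],
                                    NULL))
    for (q in seq_along(selected)) {
      vals <- t(matrix(fm[, , selected[q]], n, tt))       # T x N
      coeffs[, q, ] <- t(solve(V, vals))
    }
  }
  structure(list(coeffs = coeffs, times = seq_len(tt), modality = modality,
                 selected = selected),
            class = "poly_features")
}

#' Assemble one modality's final feature matrix
#'
#' Concatenates, for each subject, the selected raw regional values at all
#' time points with the polynomial trajectory coefficients, in a fixed
#' region-major layout: `region1_t1..region1_tT, region2_t1, ...` followed by
#' `region1_c0..region1_c(T-1), region2_c0, ...`. Column names follow the
#' scheme `<region>__t<j>` / `<region>__c<k>`. The two blocks are linearly
#' redundant by construction (the coefficients determine the raw values
#' exactly); both are kept because the fused model concatenates both.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param poly a `poly_features` from [extract_poly_features()] on the same
#'   modality and selection.
#' @return `N x (2 * D_sel * T)` numeric matrix.
#' @export
assemble_modality_matrix <- function(dataset, poly) {
  modality <- poly$modality
  fm <- dataset$features[[modality]]
  tt <- dim(fm)[2L]
  if (!identical(poly$times, seq_len(tt)))
    stop("poly features and dataset disagree on time points", call. = FALSE)
  sel <- poly$selected
  n <- dim(fm)[1L]
  if (length(sel) == 0L)
    return(matrix(0, n, 0L, dimnames = list(dataset$subject_ids, NULL)))
  regions <- dataset$region_names[[modality]][sel]
  raw <- matrix(0, n, length(sel) * tt)
  cf <- matrix(0, n, length(sel) * tt)
  raw_names <- character(length(sel) * tt)
  cf_names <- character(length(sel) * tt)
  for (q in seq_along(sel)) {
    cols <- ((q - 1L) * tt + 1L):(q * tt)
    raw[, cols] <- fm[, , sel[q]]
    cf[, cols] <- poly$coeffs[, q, ]
    raw_names[cols] <- paste0(regions[q], "__t", seq_len(tt))
    cf_names[cols] <- paste0(regions[q], "__c", 0:(tt - 1L))
  }
  out <- cbind(raw, cf)
  dimnames(out) <- list(dataset$subject_ids, c(raw_names, cf_names))
  out
}

#' Cognitive-score feature matrix
#'
#' The cognitive "modality" bypasses region selection and trajectory
#' interpolation: its feature vector is simply all clinical scores at all
#' available time points, concatenated score-major.
#'
#' @param dataset a `longitudinal_dataset`.
#' @return `N x (S * T)` matrix with columns `<score>__t<j>`.
#' @export
cognitive_feature_matrix <- function(dataset) {
  sc <- dataset$scores
  tt <- dim(sc)[2L]
  s <- dim(sc)[3L]
  out <- matrix(0, dim(sc)[1L], s * tt)
  nm <- character(s * tt)
  for (q in seq_len(s)) {
    cols <- ((q - 1L) * tt + 1L):(q * tt)
    out[, cols] <- sc[, , q]
    nm[cols] <- paste0(dataset$score_names[q], "__t", seq_len(tt))
  }
  dimnames(out) <- list(dataset$subject_ids, nm)
  out
}
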