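#' Configuration for the synthetic ADNI-like cohort generator
#'
#' Defaults emulate the reference cohort: 88 MCI subjects (38 converters, 50
#' non-converters), two imaging modalities (MRI, PET) with 93 regions each,
#' five visits at 6-month spacing (bl, M06, M12, M18, M24), and two cognitive
#' scores — an MMSE-like score in \[0, 30\] that declines in converters, and an
#' ADAS-Cog-like score that rises. Group-mean anchors (converters ~26.9 at
#' baseline declining to ~23.9 at the last visit; non-converters ~27.4 to
#' ~27.0 for MMSE; 12.7 to 16.1 / 9.6 to 11.0 for ADAS-Cog) calibrate the
#' affine score model; they are soft targets, not guarantees.
#'
#' A small informative subset of regions per modality carries the disease
#' signal: converters' informative regions follow a linear (optionally
#' quadratic) group trajectory, non-converters' a much flatter one; all other
#' regions are stationary noise around subject-specific baselines. The two
#' halves of each modality's informative set drive the MMSE-like and
#' ADAS-Cog-like scores respectively, and the two modalities' informative
#' sets overlap only partially (complementary information).
#'
#' @param n_subjects,n_converters cohort size and converter count.
#' @param modalities character names of imaging modalities.
#' @param n_regions regions per modality.
#' @param n_time_points number of visits `T` (codes 1..T, 6-month spacing).
#' @param n_informative informative regions per modality.
#' @param overlap informative regions shared between consecutive modalities.
#' @param slope_scale multiplier on the anchor-calibrated converter slopes
#'   (1 = calibrated to the score anchors).
#' @param subject_slope_sd standard deviation of the per-subject decline-rate
#'   multiplier (mean 1) applied to every informative-region slope. Decline
#'   rates in MCI cohorts are heterogeneous — follow-up score spreads fan out
#'   over time — and this heterogeneity is what makes longitudinal visits
#'   informative beyond baseline. 0 gives identical within-group slopes.
#' @param curvature quadratic coefficient of converter trajectories
#'   (default 0: linear).
#' @param noise_sd feature noise standard deviation (per region/time).
#' @param subject_sd standard deviation of subject-specific region baselines.
#' @param score_noise_sd extra Gaussian noise on scores.
#' @param mmse_anchors,adas_anchors length-4 vectors
#'   `(conv bl, conv last, nonconv bl, nonconv last)` of group-mean score
#'   anchors.
#' @param conversion_weights probabilities of conversion at months
#'   6, 12, ..., 48 (time codes 2..9); converters beyond the observed window
#'   simply keep all visits after horizon truncation.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 88L, n_converters = 38L,
                             modalities = c("MRI", "PET"), n_regions = 93L,
                             n_time_points = 5L, n_informative = 10L,
                             overlap = 5L, slope_scale = 1,
                             subject_slope_sd = 0.6,
                             curvature = 0, noise_sd = 1,
                             subject_sd = 1, score_noise_sd = 1,
                             mmse_anchors = c(26.9, 23.9, 27.4, 27.0),
                             adas_anchors = c(12.7, 16.1, 9.6, 11.0),
                             conversion_weights = c(0.12, 0.20, 0.18, 0.16,
                                                    0.12, 0.10, 0.07, 0.05),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (!(cfg$n_converters > 0L && cfg$n_converters < cfg$n_subjects))
    stop("need 0 < n_converters < n_subjects", call. = FALSE)
  if (cfg$n_informative > cfg$n_regions)
    stop("n_informative must not exceed n_regions", call. = FALSE)
  if (cfg$overlap > cfg$n_informative)
    stop("overlap must not exceed n_informative", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$subject_sd < 0 || cfg$score_noise_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (cfg$n_time_points < 1L) stop("need at least one time point", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic longitudinal multimodal cohort
#'
#' Fully seeded. Informative regions follow group-specific linear (plus
#' optional quadratic) mean trajectories around subject-specific baselines;
#' clinical scores are exact affine functions of the generated informative
#' region values plus Gaussian noise, clipped to their natural ranges
#' (\[0, 30\] for the MMSE-like score, non-negative for the ADAS-Cog-like
#' score). Converter conversion times are drawn over months 6..48.
#'
#' The affine score coefficients are solved from the group-mean anchors in
#' the configuration, so the generated group means approximate them (before
#' clipping and noise).
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a `longitudinal_dataset`) and `truth`, a list
#'   recording informative region indices per modality, per-region slopes per
#'   group, the exact score model (intercept + weights on region values),
#'   labels and conversion time codes.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  tt <- config$n_time_points
  tvec <- seq_len(tt)
  labels <- c(rep(1, config$n_converters), rep(-1, n - config$n_converters))
  subject_ids <- sprintf("S%03d", seq_len(n))
  conv <- labels == 1

  # informative sets: consecutive modalities share `overlap` regions
  informative <- list()
  prev <- NULL
  for (m in config$modalities) {
    if (is.null(prev)) {
      informative[[m]] <- sort(sample.int(config$n_regions, config$n_informative))
    } else {
      shared <- sort(sample(prev, config$overlap))
      pool <- setdiff(seq_len(config$n_regions), prev)
      fresh <- sort(sample(pool, config$n_informative - config$overlap))
      informative[[m]] <- sort(c(shared, fresh))
    }
    prev <- informative[[m]]
  }

  # Anchor-calibrated latent trajectories. Latent 1 (first half of each
  # informative set) drives the MMSE-like score with weight -1; latent 2
  # (second half) drives the ADAS-Cog-like score with weight +1.
  horizon <- max(tt - 1L, 1L)
  lat <- list(
    MMSE = latent_params(config$mmse_anchors, b = -1, horizon = horizon),
    ADAS = latent_params(config$adas_anchors, b = +1, horizon = horizon))

  # per-region role: which latent ("MMSE"/"ADAS") an informative region feeds
  roles <- lapply(informative, function(s) {
    r <- rep(c("MMSE", "ADAS"), length.out = length(s))
    stats::setNames(r, s)
  })

  # region-level slope heterogeneity, mean 1 within each latent's region set
  slope_mult <- list()
  for (m in config$modalities) {
    h <- stats::runif(length(informative[[m]]), 0.6, 1.4)
    for (sc in c("MMSE", "ADAS")) {
      idx <- which(roles[[m]] == sc)
      if (length(idx)) h[idx] <- h[idx] / mean(h[idx])
    }
    slope_mult[[m]] <- stats::setNames(h, informative[[m]])
  }

  # per-subject decline-rate multiplier, shared across regions and modalities
  subject_rate <- stats::rnorm(n, mean = 1, sd = config$subject_slope_sd)

  features <- list()
  true_slopes <- list()
  mu_list <- list()
  for (m in config$modalities) {
    d <- config$n_regions
    region_names <- sprintf("%s_R%02d", m, seq_len(d))
    mu <- stats::rnorm(d, mean = 5, sd = 1)             # region-level means
    mu_list[[m]] <- mu
    base <- matrix(stats::rnorm(n * d, sd = config$subject_sd), n, d)
    arr <- array(0, dim = c(n, tt, d),
                 dimnames = list(subject_ids, NULL, region_names))
    slopes_m <- matrix(0, d, 2, dimnames = list(region_names, c("conv", "nonconv")))
    for (k in seq_len(d)) {
      traj <- matrix(0, n, tt)
      if (k %in% informative[[m]]) {
        key <- as.character(k)
        p <- lat[[roles[[m]][key]]]
        mult <- slope_mult[[m]][key] * config$slope_scale
        off <- ifelse(conv, p$off_conv, p$off_nonconv)
        slope <- ifelse(conv, mult * p$slope_conv, mult * p$slope_nonconv) *
          subject_rate
        traj <- off + outer(slope, tvec - 1) +
          config$curvature * outer(ifelse(conv, subject_rate, 0), (tvec - 1)^2)
        slopes_m[k, ] <- c(mult * p$slope_conv, mult * p$slope_nonconv)
      }
      arr[, , k] <- mu[k] + base[, k] + traj +
        matrix(stats::rnorm(n * tt, sd = config$noise_sd), n, tt)
    }
    features[[m]] <- arr
    true_slopes[[m]] <- slopes_m
  }

  # exact affine score model over informative region values
  score_model <- list()
  for (sc in c("MMSE", "ADAS")) {
    regions <- list(); weights <- list()
    for (m in config$modalities) {
      idx <- as.integer(names(roles[[m]])[roles[[m]] == sc])
      regions[[m]] <- idx
      weights[[m]] <- rep(0, length(idx))
    }
    n_drive <- sum(lengths(regions))
    b <- if (sc == "MMSE") -1 else +1
    for (m in config$modalities)
      weights[[m]] <- rep(b / n_drive, length(regions[[m]]))
    # intercept: anchor_conv_bl = A + b * (mu-part + off_conv); the mu part
    # must be subtracted so group means land on the anchors
    score_model[[sc]] <- list(b = b, regions = regions, weights = weights,
                              off_conv = lat[[sc]]$off_conv,
                              anchor_bl = if (sc == "MMSE")
                                config$mmse_anchors[1] else config$adas_anchors[1])
  }

  scores <- array(NA_real_, dim = c(n, tt, 2),
                  dimnames = list(subject_ids, NULL, c("MMSE", "ADAS")))
  for (sc in c("MMSE", "ADAS")) {
    sm <- score_model[[sc]]
    lin <- matrix(0, n, tt)
    mu_contrib <- 0
    for (m in config$modalities) {
      idx <- sm$regions[[m]]
      for (q in seq_along(idx)) {
        k <- idx[q]
        lin <- lin + sm$weights[[m]][q] * features[[m]][, , k]
      }
    }
    # center so the converter baseline group mean lands on the anchor:
    # E[lin | conv, t=1] = sum_k w_k * (mu_k + off_conv)
    e_conv_bl <- 0
    for (m in config$modalities)
      e_conv_bl <- e_conv_bl +
        sum(sm$weights[[m]] * (mu_list[[m]][sm$regions[[m]]] + lat[[sc]]$off_conv))
    intercept <- sm$anchor_bl - e_conv_bl
    raw <- intercept + lin +
      matrix(stats::rnorm(n * tt, sd = config$score_noise_sd), n, tt)
    if (sc == "MMSE") raw <- pmin(pmax(raw, 0), 30) else raw <- pmax(raw, 0)
    scores[, , sc] <- raw
    score_model[[sc]]$intercept <- intercept
  }

  # conversion time codes (months 6..48 = codes 2..9) for converters
  conv_codes <- 2L:(1L + length(config$conversion_weights))
  conversion_time <- rep(NA_integer_, n)
  conversion_time[conv] <- sample(conv_codes, sum(conv), replace = TRUE,
                                  prob = config$conversion_weights)

  dataset <- longitudinal_dataset(subject_ids, features, scores,
                                  labels = labels)
  truth <- list(informative = informative,
                roles = roles,
                slopes = true_slopes,
                subject_rate = stats::setNames(subject_rate, subject_ids),
                score_model = score_model,
                labels = stats::setNames(labels, subject_ids),
                conversion_time = stats::setNames(conversion_time, subject_ids),
                config = config)
  list(dataset = dataset, truth = truth)
}

# Solve the latent group trajectory from score anchors (conv bl, conv last,
# nonconv bl, nonconv last) given the score's weight sign/scale b on the
# latent mean: score_mean = A + b * latent_mean.
latent_params <- function(anchors, b, horizon) {
  list(off_conv = 0,
       slope_conv = (anchors[2] - anchors[1]) / (b * horizon),
       off_nonconv = (anchors[3] - anchors[1]) / b,
       slope_nonconv = (anchors[4] - anchors[3]) / (b * horizon))
}

#' Truncate a cohort to pre-conversion horizons
#'
#' Sets each converter's usable horizon `subject_T` to one time step before
#' its conversion (a 6-month-ahead prediction setting), capped at `cap`;
#' non-converters keep `min(T, cap)` time points. Converters whose conversion
#' falls at the first visit have no usable pre-conversion data and are
#' dropped with a warning.
#'
#' @param dataset a `longitudinal_dataset` with labels.
#' @param truth ground-truth list from [generate_cohort()] (supplies
#'   conversion time codes).
#' @param cap maximum usable time points (default `T - 1`, i.e. up to the
#'   penultimate visit, mirroring "up to M18" when `T = 5`).
#' @return a `longitudinal_dataset` with `subject_T` set.
#' @export
truncate_to_horizon <- function(dataset, truth, cap = NULL) {
  tt <- length(dataset$time_codes)
  if (is.null(cap)) cap <- max(tt - 1L, 1L)
  ct <- truth$conversion_time[dataset$subject_ids]
  horizon <- ifelse(is.na(ct), cap, pmin(ct - 1L, cap))
  drop <- horizon < 1L
  if (any(drop)) {
    warning(sum(drop), " converter(s) at the first time point excluded ",
            "(no usable pre-conversion data)")
  }
  keep <- which(!drop)
  out <- subset_dataset(dataset, subjects = keep)
  out$subject_T <- as.integer(pmin(horizon[keep], tt))
  out
}
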