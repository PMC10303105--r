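# Synthetic cohort generator. Emulates the four-group structure the
# analyses assume (two ALCL groups and CD30-high/low PTCL, NOS) with
# configurable H-score distributions, TILs composite scores, clinical
# covariate prevalences and censored exponential survival. Fully
# reproducible given (config, seed).

#' Describe an H-score sampling distribution
#'
#' H-score targets are drawn from a Beta distribution rescaled to
#' \[`lo`, `hi`\] whose median is matched exactly to `median` by solving
#' for the first shape parameter at the given concentration
#' (`shape1 + shape2`). Lower concentration means wider dispersion;
#' `concentration = Inf` gives a point mass at the median.
#'
#' @param median Target distribution median on the score scale.
#' @param concentration Sum of Beta shape parameters (> 0), or `Inf`.
#' @param lo,hi Support bounds (default the H-score scale \[0, 300\]).
#' @return A `score_dist` list.
#' @export
score_dist <- function(median, concentration, lo = 0, hi = 300) {
  stopifnot(median >= lo, median <= hi, concentration > 0)
  structure(list(median = median, concentration = concentration,
                 lo = lo, hi = hi),
            class = "score_dist")
}

beta_shape_for_median <- function(q, k) {
  # solve qbeta(0.5, a, k - a) = q for a in (0, k)
  if (q <= 0) return(1e-8)
  if (q >= 1) return(k - 1e-8)
  # qbeta warns at the extreme shapes uniroot probes; the root itself is
  # checked by the median-recovery tests
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, k - a)) - q
  stats::uniroot(f, c(1e-8, k - 1e-8), tol = 1e-12)$root
}

#' @describeIn score_dist Quantile function of a `score_dist` (used to
#'   transform uniform or Gaussian-copula draws into scores).
#' @param dist A `score_dist`.
#' @param p Probabilities.
#' @export
q_score_dist <- function(dist, p) {
  stopifnot(inherits(dist, "score_dist"))
  if (is.infinite(dist$concentration)) {
    return(rep(dist$median, length(p)))
  }
  q <- (dist$median - dist$lo) / (dist$hi - dist$lo)
  a <- beta_shape_for_median(q, dist$concentration)
  dist$lo + (dist$hi - dist$lo) * stats::qbeta(p, a, dist$concentration - a)
}

#' Turn target H-scores into staining profiles
#'
#' Back-fills a staining-intensity profile whose H-score equals the
#' target exactly: a fraction `1 - dispersion` of the score mass is
#' allocated to strong (3+) staining and the remainder to moderate (2+),
#' falling back to the unique 3+/2+ split when the cell budget would be
#' exceeded (possible only for scores above 200). Many profiles share an
#' H-score; this deterministic rule keeps the generator reproducible.
#'
#' @param h Numeric vector of H-scores in \[0, 300\].
#' @param dispersion Fraction of score mass shifted below 3+ (default
#'   0.3).
#' @return Tibble with columns `frac0` ... `frac3`;
#'   `h_score(frac0, ..., frac3)` reproduces `h` exactly.
#' @export
profile_from_hscore <- function(h, dispersion = 0.3) {
  stopifnot(all(h >= 0 & h <= 300), dispersion >= 0, dispersion < 1)
  f3 <- (1 - dispersion) * h / 300
  f2 <- dispersion * h / 200
  over <- f3 + f2 > 1
  f3[over] <- pmin(1, pmax(0, (h[over] - 200) / 100))
  f2[over] <- 1 - f3[over]
  tibble(frac0 = pmax(0, 1 - f2 - f3), frac1 = 0, frac2 = f2, frac3 = f3)
}

default_missingness <- function() {
  c(ecog_gt1 = 0.06, ldh_elevated = 0.18, stage_advanced = 0.06,
    bm_involvement = 0.5, b2m_high = 0.55, platelet_low = 0.03,
    response_crpr = 0.1, ipi_high = 0.06)
}

#' Specify one synthetic cohort group
#'
#' @param label Subgroup label (also the case-id prefix).
#' @param diagnosis Diagnosis recorded on each case.
#' @param n Number of cases.
#' @param tumor_markers Named list of [score_dist()] for tumor-cell
#'   H-scores (`y705`, `s727`, `cd30`).
#' @param marker_correlation Gaussian-copula correlation between the
#'   Y705 and S727 tumor scores within a case (rank-correlation scale,
#'   default 0.5 — the within-case coupling of the two phosphosites is
#'   an assumption, not an observed quantity).
#' @param cd30_range Range of the CD30 percent-positive fraction
#'   (uniform draw).
#' @param tils List: `p_no_tils` (probability of a TILs-free tumor),
#'   `composite` ([score_dist()] of the TILs-weighted S727 composite
#'   among TILs-bearing cases) and `tils_hscore` ([score_dist()] of the
#'   raw S727 H-score in TILs).
#' @param survival List: `median_months` (exponential event-time
#'   median; `Inf` for event-free), `censor_range` (uniform
#'   administrative censoring window, months), `p_lost` (probability of
#'   loss to follow-up, i.e. missing outcome).
#' @param age List: `mean`, `sd`, `min`, `max` for a clipped normal.
#' @param covariates Named prevalence vector for the logical clinical
#'   covariates plus `male`.
#' @param missingness Named per-covariate missingness probabilities.
#' @param mpit_probs Probabilities of modified-PIT scores 0:3, or
#'   `NULL` when the index is not recorded for the group.
#' @param dispersion Profile back-fill dispersion
#'   ([profile_from_hscore()]).
#' @return A `cohort_group_spec` list.
#' @export
cohort_group_spec <- function(label, diagnosis, n, tumor_markers,
                              marker_correlation = 0.5,
                              cd30_range = c(0.85, 1),
                              tils = list(
                                p_no_tils = 0.1,
                                composite = score_dist(15, 2),
                                tils_hscore = score_dist(130, 4)
                              ),
                              survival = list(median_months = 60,
                                              censor_range = c(12, 72),
                                              p_lost = 0.1),
                              age = list(mean = 60, sd = 12,
                                         min = 18, max = 90),
                              covariates = c(male = 0.6),
                              missingness = default_missingness(),
                              mpit_probs = NULL,
                              dispersion = 0.3) {
  stopifnot(n >= 0, diagnosis %in% DIAGNOSIS_LEVELS,
            marker_correlation >= -1, marker_correlation <= 1)
  if (!is.null(mpit_probs)) {
    stopifnot(length(mpit_probs) == 4, abs(sum(mpit_probs) - 1) < 1e-8)
  }
  structure(
    list(label = label, diagnosis = diagnosis, n = n,
         tumor_markers = tumor_markers,
         marker_correlation = marker_correlation,
         cd30_range = cd30_range, tils = tils, survival = survival,
         age = age, covariates = covariates, missingness = missingness,
         mpit_probs = mpit_probs, dispersion = dispersion),
    class = "cohort_group_spec"
  )
}

#' Default study configuration
#'
#' The configuration the package's worked examples and acceptance checks
#' use: an 89-case cohort of four groups — ALK-positive ALCL (n = 33),
#' ALK-negative ALCL (n = 22), CD30-high PTCL, NOS (n = 10) and
#' CD30-low PTCL, NOS (n = 24) — with tumor H-score medians of 280/260
#' (ALK+), 250/240 (ALK-), 45/75 (CD30-high) and 65/105 (CD30-low) for
#' pSTAT3-Y705/S727, TILs composite medians of 10/18/14.5/31, a PTCL,
#' NOS exponential survival median of 5.0 months, and ALCL survival
#' reaching no median within the follow-up window. Marker dispersions
#' are fixed so the implied ALK-negative-ALCL vs CD30-high
#' discrimination is in the high-0.8 to low-0.9 AUC range.
#'
#' @return A `cohort_config` object (list of group specs); two calls
#'   return identical configurations.
#' @export
default_study_config <- function() {
  groups <- list(
    cohort_group_spec(
      label = "ALKpos", diagnosis = "ALK_POS_ALCL", n = 33,
      tumor_markers = list(y705 = score_dist(280, 3),
                           s727 = score_dist(260, 3),
                           cd30 = score_dist(295, 12)),
      cd30_range = c(0.9, 1),
      tils = list(p_no_tils = 0.1,
                  composite = score_dist(10, 2),
                  tils_hscore = score_dist(110, 4)),
      survival = list(median_months = 130, censor_range = c(20, 90),
                      p_lost = 0.08),
      age = list(mean = 30, sd = 15, min = 5, max = 70),
      covariates = c(male = 0.82, ecog_gt1 = 0.16, ldh_elevated = 0.52,
                     stage_advanced = 0.50, bm_involvement = 0.05,
                     b2m_high = 0.44, platelet_low = 0.03,
                     response_crpr = 0.71, ipi_high = 0.13)
    ),
    cohort_group_spec(
      label = "ALKneg", diagnosis = "ALK_NEG_ALCL", n = 22,
      tumor_markers = list(y705 = score_dist(250, 1.4),
                           s727 = score_dist(240, 3),
                           cd30 = score_dist(290, 12)),
      cd30_range = c(0.85, 1),
      tils = list(p_no_tils = 0.1,
                  composite = score_dist(18, 2),
                  tils_hscore = score_dist(120, 4)),
      survival = list(median_months = 110, censor_range = c(15, 85),
                      p_lost = 0.1),
      age = list(mean = 60, sd = 12, min = 29, max = 77),
      covariates = c(male = 0.62, ecog_gt1 = 0.18, ldh_elevated = 0.33,
                     stage_advanced = 0.59, bm_involvement = 0.25,
                     b2m_high = 0.14, platelet_low = 0.17,
                     response_crpr = 0.50, ipi_high = 0.18)
    ),
    cohort_group_spec(
      label = "CD30high", diagnosis = "PTCL_NOS", n = 10,
      tumor_markers = list(y705 = score_dist(45, 1.4),
                           s727 = score_dist(75, 3),
                           cd30 = score_dist(240, 12)),
      cd30_range = c(0.80, 1),
      tils = list(p_no_tils = 0.18,
                  composite = score_dist(14.5, 2),
                  tils_hscore = score_dist(120, 4)),
      survival = list(median_months = 5, censor_range = c(24, 60),
                      p_lost = 0.18),
      age = list(mean = 62, sd = 13, min = 32, max = 85),
      covariates = c(male = 0.50, ecog_gt1 = 0.30, ldh_elevated = 0.50,
                     stage_advanced = 0.80, bm_involvement = 0.33,
                     b2m_high = 0.33, platelet_low = 0.50,
                     response_crpr = 0.10, ipi_high = 0.30),
      mpit_probs = c(0.25, 0.35, 0.25, 0.15)
    ),
    cohort_group_spec(
      label = "CD30low", diagnosis = "PTCL_NOS", n = 24,
      tumor_markers = list(y705 = score_dist(65, 1.4),
                           s727 = score_dist(105, 3),
                           cd30 = score_dist(80, 2)),
      cd30_range = c(0.02, 0.75),
      tils = list(p_no_tils = 0.18,
                  composite = score_dist(31, 2),
                  tils_hscore = score_dist(130, 4)),
      survival = list(median_months = 5, censor_range = c(24, 60),
                      p_lost = 0.18),
      age = list(mean = 58, sd = 13, min = 28, max = 76),
      covariates = c(male = 0.71, ecog_gt1 = 0.17, ldh_elevated = 0.64,
                     stage_advanced = 0.78, bm_involvement = 0.29,
                     b2m_high = 0.85, platelet_low = 0.17,
                     response_crpr = 0.02, ipi_high = 0.52),
      mpit_probs = c(0.25, 0.35, 0.25, 0.15)
    )
  )
  structure(list(groups = groups), class = "cohort_config")
}

#' Two-group configuration with planted score separation
#'
#' Builds a minimal two-group configuration (ALK-negative ALCL, n = 22,
#' versus CD30-high PTCL, NOS, n = 10) whose S727 tumor scores are
#' planted at the given medians; in the infinite-data limit the
#' Youden-optimal cutoff lies between them. `overlap` controls
#' discrimination: 0 gives zero-variance point masses at the medians
#' (AUC 1); larger values widen both distributions
#' (Beta concentration `4 / overlap`); `Inf` collapses both groups onto
#' one common distribution at the midpoint of the medians (AUC 0.5 in
#' expectation).
#'
#' @param median_pos,median_neg Planted medians for the positive
#'   (ALK-negative ALCL) and negative (CD30-high PTCL, NOS) group, in
#'   \[0, 300\].
#' @param overlap Non-negative dispersion scale (default 1), or `Inf`.
#' @param n_pos,n_neg Group sizes (defaults 22 and 10).
#' @return A `cohort_config`.
#' @export
planted_separation_config <- function(median_pos = 240, median_neg = 75,
                                      overlap = 1, n_pos = 22, n_neg = 10) {
  stopifnot(median_pos >= 0, median_pos <= 300,
            median_neg >= 0, median_neg <= 300, overlap >= 0)
  if (is.infinite(overlap)) {
    m <- (median_pos + median_neg) / 2
    d_pos <- d_neg <- score_dist(m, 2)
  } else if (overlap == 0) {
    d_pos <- score_dist(median_pos, Inf)
    d_neg <- score_dist(median_neg, Inf)
  } else {
    d_pos <- score_dist(median_pos, 4 / overlap)
    d_neg <- score_dist(median_neg, 4 / overlap)
  }
  base <- default_study_config()$groups
  pos <- base[[2]]; neg <- base[[3]]
  pos$n <- n_pos; neg$n <- n_neg
  pos$tumor_markers$s727 <- d_pos
  neg$tumor_markers$s727 <- d_neg
  structure(list(groups = list(pos, neg)), class = "cohort_config")
}

sample_group <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n
  if (n == 0) return(NULL)
  out <- tibble(
    case_id = sprintf("%s_%03d", spec$label, seq_len(n)),
    diagnosis = spec$diagnosis
  )
  # tumor marker scores: Gaussian copula couples Y705 and S727
  z1 <- rnorm(n); e <- rnorm(n)
  rho <- spec$marker_correlation
  z2 <- rho * z1 + sqrt(1 - rho^2) * e
  hs <- list(
    y705 = q_score_dist(spec$tumor_markers$y705, pnorm(z1)),
    s727 = q_score_dist(spec$tumor_markers$s727, pnorm(z2)),
    cd30 = q_score_dist(spec$tumor_markers$cd30, runif(n))
  )
  for (m in names(hs)) {
    prof <- profile_from_hscore(hs[[m]], spec$dispersion)
    names(prof) <- profile_cols(m, "tumor")
    out <- dplyr::bind_cols(out, prof)
  }
  out$cd30_frac <- runif(n, spec$cd30_range[1], spec$cd30_range[2])
  # TILs: composite score first, then a raw TILs H-score at least as
  # large, so tils_frac = composite / hscore lies in (0, 1]
  no_tils <- runif(n) < spec$tils$p_no_tils
  comp <- q_score_dist(spec$tils$composite, runif(n))
  t_raw <- q_score_dist(spec$tils$tils_hscore, runif(n))
  frac_when_zero <- runif(n, 0.05, 0.5)
  t_hs <- pmax(t_raw, comp)
  tils_frac <- ifelse(t_hs > 0, comp / t_hs, frac_when_zero)
  tils_frac[no_tils] <- 0
  s727_tils <- profile_from_hscore(ifelse(no_tils, 0, t_hs), spec$dispersion)
  s727_tils[no_tils, ] <- NA_real_
  names(s727_tils) <- profile_cols("s727", "tils")
  y705_tils <- profile_from_hscore(rep(0, n))
  y705_tils[no_tils, ] <- NA_real_
  names(y705_tils) <- profile_cols("y705", "tils")
  out <- dplyr::bind_cols(out, tibble(tils_frac = tils_frac),
                          s727_tils, y705_tils)
  # survival: exponential event times, uniform administrative censoring
  med <- spec$survival$median_months
  event_t <- if (is.infinite(med)) rep(Inf, n) else rexp(n, log(2) / med)
  cens_t <- runif(n, spec$survival$censor_range[1],
                  spec$survival$censor_range[2])
  os_months <- pmin(event_t, cens_t)
  os_event <- event_t <= cens_t
  lost <- runif(n) < spec$survival$p_lost
  os_months[lost] <- NA_real_
  os_event[lost] <- NA
  out$os_months <- os_months
  out$os_event <- os_event
  # clinical covariates
  out$age <- round(pmin(spec$age$max, pmax(spec$age$min,
                                           rnorm(n, spec$age$mean, spec$age$sd))))
  p_male <- spec$covariates[["male"]] %||% 0.6
  out$sex <- ifelse(runif(n) < p_male, "M", "F")
  for (cv in CLINICAL_LOGICAL) {
    p <- spec$covariates[cv]
    v <- if (is.na(p)) rep(NA, n) else runif(n) < p
    p_miss <- spec$missingness[cv]
    if (!is.na(p_miss) && p_miss > 0) v[runif(n) < p_miss] <- NA
    out[[cv]] <- v
  }
  out$mpit_score <- if (is.null(spec$mpit_probs)) {
    rep(NA_integer_, n)
  } else {
    as.integer(sample(0:3, n, replace = TRUE, prob = spec$mpit_probs))
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from a configuration. Each group is sampled from its
#' own deterministic substream derived from the root seed, so adding or
#' reordering groups does not perturb the draws of the others, and the
#' same (config, seed) pair always reproduces the identical cohort.
#'
#' @param config A `cohort_config` (e.g. [default_study_config()]).
#' @param seed Integer root seed.
#' @return A validated cohort tibble; provenance records the seed and a
#'   hash of the configuration.
#' @export
generate_cohort <- function(config = default_study_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- map(config$groups, "label")
  if (anyDuplicated(unlist(labels))) {
    abort("generate_cohort: duplicate group labels",
          class = "ihcdx_config_error")
  }
  parts <- imap(config$groups, function(spec, i) {
    sample_group(spec, (seed + 7919L * i) %% .Machine$integer.max)
  })
  data <- list_rbind(keep(parts, ~ !is.null(.x)))
  as_cohort(data,
            provenance = paste0("generate_cohort(seed=", seed,
                                ", config=", hash(config), ")"))
}
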