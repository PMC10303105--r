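# Right-censored survival analysis: product-limit (Kaplan-Meier)
# estimation, log-rank testing, TILs-score prognostic stratification and
# additive clinical risk indices. Time unit is months throughout.

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored times. At tied
#' times, deaths are processed before censorings (the standard
#' product-limit convention), so a censoring at an event time still
#' counts in the risk set of that event.
#'
#' @param times Non-negative follow-up times in months.
#' @param events Logical, `TRUE` = death observed, `FALSE` = censored.
#' @return An object of class `ihc_km`: a list with `steps` (tibble of
#'   distinct observed times with `n_risk`, `n_event`, `n_censor`,
#'   `survival`) and `n`.
#' @export
km_estimate <- function(times, events) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- as.logical(events[keep])
  if (length(times) == 0) {
    abort("km_estimate: no usable observations",
          class = "ihcdx_validation_error")
  }
  if (any(times < 0)) {
    abort("km_estimate: negative times", class = "ihcdx_validation_error")
  }
  ut <- sort(unique(times))
  idx <- match(times, ut)
  n_event <- tabulate(idx[events], nbins = length(ut))
  n_censor <- tabulate(idx[!events], nbins = length(ut))
  tot <- n_event + n_censor
  n_risk <- length(times) - c(0L, cumsum(tot)[-length(ut)])
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(steps = tibble(time = ut, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, survival = surv),
         n = length(times)),
    class = "ihc_km"
  )
}

#' @export
print.ihc_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: n = ", x$n, ", ", sum(x$steps$n_event),
      " events\n", sep = "")
  med <- median_survival(x)
  cat("  median survival: ",
      if (is.na(med)) "not reached" else paste(format(med), "months"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ihc_km <- function(x, ...) x$steps

#' @export
glance.ihc_km <- function(x, ...) {
  tibble(n = x$n, events = sum(x$steps$n_event),
         median_survival = median_survival(x),
         os_36 = survival_at(x, 36))
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of the product-limit estimate;
#' the 3-year overall-survival rate is `survival_at(km, 36)`.
#'
#' @param km An `ihc_km` object.
#' @param t Time in months (vectorised).
#' @return Estimated S(t) in \[0, 1\]; beyond the last observed time the
#'   last estimate is carried forward.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "ihc_km"), all(t >= 0))
  map_dbl(t, function(tt) {
    idx <- which(km$steps$time <= tt)
    if (length(idx) == 0) 1 else km$steps$survival[max(idx)]
  })
}

#' Median survival time
#'
#' The smallest observed event time at which the survival estimate drops
#' to 0.5 or below (no interpolation); `NA` when the curve never reaches
#' 0.5 ("not reached").
#'
#' @param km An `ihc_km` object.
#' @return Months, or `NA_real_` when not reached.
#' @export
median_survival <- function(km) {
  stopifnot(inherits(km, "ihc_km"))
  hit <- km$steps$time[km$steps$survival <= 0.5 + 1e-12]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' Log-rank test across survival groups
#'
#' Standard k-group log-rank chi-square: at each pooled distinct event
#' time the observed events per group are compared with their
#' hypergeometric expectation given the risk sets, and the accumulated
#' observed-minus-expected vector is tested against its hypergeometric
#' covariance. p from chi-square with k - 1 degrees of freedom.
#'
#' @param times Follow-up times in months.
#' @param events Logical event indicators.
#' @param group Group membership vector (2 or more non-empty groups).
#' @return One-row tibble: `statistic` (chi-square), `p_value`,
#'   `method`, `n`, `degenerate` (`TRUE` when no events occur anywhere,
#'   in which case p = 1), `df`.
#' @export
logrank_test <- function(times, events, group) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- as.logical(events[keep])
  group <- as.character(group[keep])
  lv <- unique(group)
  k <- length(lv)
  if (k < 2) {
    abort("logrank_test: need at least two groups",
          class = "ihcdx_validation_error")
  }
  n <- length(times)
  ev_times <- sort(unique(times[events]))
  if (length(ev_times) == 0) {
    return(mutate(test_result(0, 1, "log-rank (degenerate)", n,
                              degenerate = TRUE), df = k - 1L))
  }
  gi <- match(group, lv)
  # per-group risk-set sizes and event counts at every pooled event time
  risk_mat <- vapply(seq_len(k), function(g) {
    st <- sort(times[gi == g])
    length(st) - findInterval(ev_times, st, left.open = TRUE)
  }, numeric(length(ev_times)))
  death_mat <- vapply(seq_len(k), function(g) {
    tabulate(match(times[events & gi == g], ev_times),
             nbins = length(ev_times))
  }, numeric(length(ev_times)))
  o_minus_e <- setNames(numeric(k), lv)
  v <- matrix(0, k, k, dimnames = list(lv, lv))
  for (i in seq_along(ev_times)) {
    n_g <- risk_mat[i, ]
    n_t <- sum(n_g)
    d_t <- sum(death_mat[i, ])
    o_minus_e <- o_minus_e + (death_mat[i, ] - d_t * n_g / n_t)
    if (n_t > 1) {
      mult <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      v <- v + mult * (diag(n_g * n_t, k) - outer(n_g, n_g))
    }
  }
  # drop one group: the covariance matrix is singular by construction
  sub <- seq_len(k - 1)
  vi <- tryCatch(solve(v[sub, sub, drop = FALSE]), error = function(e) NULL)
  if (is.null(vi)) {
    return(mutate(test_result(0, 1, "log-rank (degenerate)", n,
                              degenerate = TRUE), df = k - 1L))
  }
  stat <- drop(t(o_minus_e[sub]) %*% vi %*% o_minus_e[sub])
  mutate(test_result(stat, stats::pchisq(stat, k - 1, lower.tail = FALSE),
                     "log-rank", n),
         df = k - 1L)
}

#' Stratify PTCL, NOS cases by the TILs composite score
#'
#' Three-way prognostic stratification on the TILs-weighted pSTAT3-S727
#' composite score: cases with no TILs (`tils_frac = 0`) form their own
#' group; the remaining cases split at the cohort median of the
#' composite score into `LOW` (below the split) and `HIGH` (at or above
#' it). Cases without follow-up (`os_months` missing) or without a
#' usable score are flagged `EXCLUDED` and do not enter the median.
#'
#' @param data A scored cohort tibble (needs `s727_tils_score`,
#'   `tils_frac`, `os_months`); non-PTCL, NOS rows are excluded.
#' @param include_no_tils_in_median Include the zero scores of no-TILs
#'   cases when computing the split value (default `TRUE`).
#' @return The input tibble with a `tils_group` column (`NO_TILS`,
#'   `LOW`, `HIGH`, `EXCLUDED`); the split value is attached as
#'   attribute `split_value` and returned by [tils_split_value()].
#' @export
stratify_by_tils_score <- function(data, include_no_tils_in_median = TRUE) {
  if (!"s727_tils_score" %in% names(data)) {
    abort("stratify_by_tils_score: run score_cohort() first",
          class = "ihcdx_schema_error")
  }
  included <- data$diagnosis == "PTCL_NOS" &
    !is.na(data$os_months) & !is.na(data$s727_tils_score)
  med_pool <- included & (include_no_tils_in_median |
                            is.na(data$tils_frac) | data$tils_frac > 0)
  split_value <- median(data$s727_tils_score[med_pool])
  grp <- rep("EXCLUDED", nrow(data))
  no_tils <- included & !is.na(data$tils_frac) & data$tils_frac == 0
  grp[included & !no_tils & data$s727_tils_score < split_value] <- "LOW"
  grp[included & !no_tils & data$s727_tils_score >= split_value] <- "HIGH"
  grp[no_tils] <- "NO_TILS"
  out <- mutate(data, tils_group = grp)
  attr(out, "split_value") <- split_value
  out
}

#' @describeIn stratify_by_tils_score Retrieve the split value from a
#'   stratified cohort.
#' @export
tils_split_value <- function(data) attr(data, "split_value")

#' Define an additive clinical risk index
#'
#' A risk index counts how many adverse factors a case satisfies and
#' maps the count to a risk label. Factors are one-sided formulas
#' evaluated in the cohort (e.g. `~ age > 60`); the grouping maps score
#' ranges to labels via inclusive breaks.
#'
#' @param name Index name.
#' @param factors Named list of one-sided formulas, one per adverse
#'   factor.
#' @param grouping Named list `label -> integer vector of scores`.
#' @return A `risk_index_definition` object.
#' @export
risk_index_definition <- function(name, factors, grouping) {
  stopifnot(is.character(name), is.list(factors), length(factors) >= 1,
            is.list(grouping))
  if (!all(map_lgl(factors, ~ inherits(.x, "formula")))) {
    abort("risk_index_definition: factors must be one-sided formulas",
          class = "ihcdx_config_error")
  }
  covered <- sort(unique(unlist(grouping)))
  if (!all(0:length(factors) %in% covered)) {
    abort("risk_index_definition: grouping must cover scores 0..n_factors",
          class = "ihcdx_config_error")
  }
  structure(list(name = name, factors = factors, grouping = grouping),
            class = "risk_index_definition")
}

#' The PIT prognostic index
#'
#' Prognostic Index for T-cell lymphoma: one point each for age above
#' 60 years, ECOG performance status above 1, elevated LDH, and bone
#' marrow involvement; 0-1 factors = low risk, 2 or more = high risk.
#'
#' @return A [risk_index_definition()].
#' @export
pit_definition <- function() {
  risk_index_definition(
    name = "PIT",
    factors = list(
      age_gt60 = ~ age > 60,
      ecog_gt1 = ~ ecog_gt1,
      ldh_elevated = ~ ldh_elevated,
      bm_involvement = ~ bm_involvement
    ),
    grouping = list(low = 0:1, high = 2:4)
  )
}

#' Score a cohort against a risk index
#'
#' Counts satisfied adverse factors per case and maps the count through
#' the index grouping. Cases missing any factor covariate are labelled
#' `EXCLUDED` with score `NA`. A modified-PIT style index can be passed
#' as a user-supplied [risk_index_definition()] with its published
#' factor set and the 0-1 low / 2-3 high grouping.
#'
#' @param data A cohort tibble.
#' @param definition A [risk_index_definition()].
#' @return The tibble with `risk_score` (integer) and `risk_group`
#'   columns appended (column names prefixed by the index name in lower
#'   case).
#' @export
risk_index_score <- function(data, definition = pit_definition()) {
  stopifnot(inherits(definition, "risk_index_definition"))
  vals <- map(definition$factors, function(f) {
    res <- tryCatch(eval_tidy(f[[2]], data = data),
                    error = function(e) {
                      abort(paste0("risk_index_score: cannot evaluate factor ",
                                   deparse(f[[2]]), ": ", conditionMessage(e)),
                            class = "ihcdx_config_error")
                    })
    as.logical(res)
  })
  m <- do.call(cbind, vals)
  score <- rowSums(m)
  score[rowSums(is.na(m)) > 0] <- NA
  lab <- rep("EXCLUDED", nrow(data))
  for (g in names(definition$grouping)) {
    lab[!is.na(score) & score %in% definition$grouping[[g]]] <- g
  }
  pre <- tolower(definition$name)
  data[[paste0(pre, "_score")]] <- as.integer(score)
  data[[paste0(pre, "_group")]] <- lab
  data
}

#' Kaplan-Meier curves and log-rank test per group
#'
#' Convenience wrapper computing one [km_estimate()] per level of a
#' grouping column plus the [logrank_test()] across groups with at
#' least one case.
#'
#' @param data A cohort tibble with `os_months`, `os_event`.
#' @param by Grouping column name; rows with `NA` or values in
#'   `exclude` are dropped.
#' @param exclude Group labels to drop (default `"EXCLUDED"`).
#' @return List with `curves` (named list of `ihc_km`), `logrank`
#'   (tibble, `NULL` if fewer than two groups), and `summary` tibble
#'   (group, n, events, median OS, OS at 12/36/60 months).
#' @export
survival_by_group <- function(data, by, exclude = "EXCLUDED") {
  keep <- !is.na(data[[by]]) & !(data[[by]] %in% exclude) &
    !is.na(data$os_months) & !is.na(data$os_event)
  d <- data[keep, ]
  if (nrow(d) == 0) {
    abort("survival_by_group: no usable cases",
          class = "ihcdx_validation_error")
  }
  groups <- unique(d[[by]])
  curves <- setNames(
    map(groups, ~ km_estimate(d$os_months[d[[by]] == .x],
                              d$os_event[d[[by]] == .x])),
    groups
  )
  summary <- list_rbind(imap(curves, function(km, g) {
    tibble(group = g, n = km$n, events = sum(km$steps$n_event),
           median_os = median_survival(km),
           os_12 = survival_at(km, 12), os_36 = survival_at(km, 36),
           os_60 = survival_at(km, 60))
  }))
  lr <- if (length(groups) >= 2) {
    logrank_test(d$os_months, d$os_event, d[[by]])
  } else NULL
  list(curves = curves, logrank = lr, summary = summary)
}
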