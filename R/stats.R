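# Exact group-comparison statistics implemented from first principles:
# two-sided Fisher exact test, Mann-Whitney U (exact and tie-corrected
# normal approximation), Kruskal-Wallis, Spearman rank correlation, and a
# cohort-level dispatcher mirroring a clinical Table-1 comparison.

test_result <- function(statistic, p_value, method, n, degenerate = FALSE) {
  tibble(statistic = statistic, p_value = p_value, method = method,
         n = as.integer(n), degenerate = degenerate)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities
#' of all tables whose point probability does not exceed that of the
#' observed table (the probability-mass definition of the two-sided
#' test, with a relative slack of 1e-7 guarding floating-point
#' comparisons of equal masses). The reported statistic is the observed
#' table's point probability.
#'
#' @param a,b,c,d Cell counts: rows are groups, columns outcome
#'   present/absent, so the table is `rbind(c(a, b), c(c, d))`.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n`,
#'   `degenerate` (`TRUE` when a zero margin makes the table
#'   uninformative, in which case p = 1).
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("fisher_exact_two_sided: counts must be non-negative integers",
          class = "ihcdx_validation_error")
  }
  n <- sum(counts)
  r1 <- a + b; c1 <- a + c; c2 <- b + d; r2 <- c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(test_result(1, 1, "Fisher exact (two-sided)", n, degenerate = TRUE))
  }
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(k, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  test_result(p_obs, p, "Fisher exact (two-sided)", n)
}

midranks <- function(v) rank(v, ties.method = "average")

tie_correction_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples with mid-rank tie handling.
#' The statistic is U for `x` (number of (x, y) pairs with x above y,
#' ties counting one half). In `exact` mode the null distribution is
#' built by exhaustive enumeration of all `choose(n, n_x)` assignments
#' of the pooled mid-ranks and the two-sided p doubles the smaller tail
#' (capped at 1). `normal` mode uses the tie-corrected normal
#' approximation, without continuity correction unless `correct = TRUE`.
#' `auto` picks exact for pooled n of at most 12.
#'
#' @param x,y Numeric samples (non-empty; `NA` dropped).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param correct Continuity correction in normal mode.
#' @return One-row tibble as [fisher_exact_two_sided()]; `statistic` is
#'   U for `x`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           correct = FALSE) {
  mode <- arg_match(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) {
    abort("mann_whitney_u: both samples must be non-empty",
          class = "ihcdx_validation_error")
  }
  pooled <- c(x, y)
  r <- midranks(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  method <- "Mann-Whitney U"
  if (length(unique(pooled)) == 1) {
    return(test_result(u, 1, paste(method, "(degenerate)"), n,
                       degenerate = TRUE))
  }
  if (mode == "auto") mode <- if (n <= 12) "exact" else "normal"
  if (mode == "exact") {
    combos <- combn(n, nx)
    us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    lo <- mean(us <= u + 1e-9); hi <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    return(test_result(u, p, paste(method, "(exact)"), n))
  }
  var_u <- nx * ny / 12 *
    ((n + 1) - tie_correction_term(pooled) / (n * (n - 1)))
  if (var_u <= 0) {
    return(test_result(u, 1, paste(method, "(degenerate)"), n,
                       degenerate = TRUE))
  }
  centred <- u - nx * ny / 2
  if (correct) centred <- sign(centred) * max(0, abs(centred) - 0.5)
  z <- centred / sqrt(var_u)
  test_result(u, min(1, 2 * pnorm(-abs(z))),
              paste(method, "(normal approximation)"), n)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic over two or more groups, with the p-value
#' from the chi-square distribution on k - 1 degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return One-row tibble as [fisher_exact_two_sided()]; `statistic` is
#'   H.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("kruskal_wallis: need at least two non-empty groups",
          class = "ihcdx_validation_error")
  }
  pooled <- unlist(groups)
  n <- length(pooled)
  k <- length(groups)
  if (length(unique(pooled)) == 1) {
    return(test_result(0, 1, "Kruskal-Wallis (degenerate)", n,
                       degenerate = TRUE))
  }
  r <- midranks(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) *
    sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
  h <- h / (1 - tie_correction_term(pooled) / (n^3 - n))
  test_result(h, stats::pchisq(h, df = k - 1, lower.tail = FALSE),
              "Kruskal-Wallis", n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, length at least 3 after dropping
#'   incomplete pairs.
#' @return One-row tibble as [fisher_exact_two_sided()]; `statistic` is
#'   rho.
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("spearman_rho: need at least 3 complete pairs",
          class = "ihcdx_validation_error")
  }
  rx <- midranks(x); ry <- midranks(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("spearman_rho: rank variance is zero, rho undefined",
          class = "ihcdx_degenerate_error")
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- min(1, 2 * pt(-abs(t_stat), df = n - 2))
  }
  test_result(rho, p, "Spearman rank correlation", n)
}

#' Compare a covariate between two cohort groups
#'
#' Builds the comparison the clinical baseline tables perform: for a
#' logical covariate, a 2x2 Fisher exact test of covariate prevalence
#' between the groups; for a numeric covariate, a Mann-Whitney U test.
#' Missing covariate values are excluded pairwise, so denominators vary
#' per covariate. The realised 2x2 table or samples are returned in an
#' `audit` list-column so every p-value is traceable.
#'
#' @param data A cohort tibble.
#' @param covariate Covariate column name (string); logical dispatches
#'   to Fisher, numeric to Mann-Whitney U.
#' @param by Grouping column name (e.g. `"diagnosis"` or `"subgroup"`).
#' @param group_a,group_b Values of `by` defining the two groups.
#' @param mwu_mode Passed to [mann_whitney_u()].
#' @return One-row tibble: `covariate`, `group_a`, `group_b`, `method`,
#'   `statistic`, `p_value`, `n`, `degenerate`, `audit` (list-column).
#' @export
compare_groups <- function(data, covariate, by, group_a, group_b,
                           mwu_mode = "auto") {
  for (col in c(covariate, by)) {
    if (!col %in% names(data)) {
      abort(paste0("compare_groups: no column '", col, "'"),
            class = "ihcdx_schema_error")
    }
  }
  va <- data[[covariate]][data[[by]] %in% group_a]
  vb <- data[[covariate]][data[[by]] %in% group_b]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0) {
    abort(paste0("compare_groups: no non-missing '", covariate,
                 "' values in one of the groups"),
          class = "ihcdx_validation_error")
  }
  if (is.logical(data[[covariate]])) {
    tab <- matrix(c(sum(va), sum(!va), sum(vb), sum(!vb)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(group = c(paste(group_a, collapse = "+"),
                                            paste(group_b, collapse = "+")),
                                  outcome = c("yes", "no")))
    res <- fisher_exact_two_sided(tab)
    audit <- list(table = tab)
  } else if (is.numeric(data[[covariate]])) {
    res <- mann_whitney_u(va, vb, mode = mwu_mode)
    audit <- list(x = va, y = vb)
  } else {
    abort(paste0("compare_groups: covariate '", covariate,
                 "' must be logical or numeric"),
          class = "ihcdx_validation_error")
  }
  mutate(res,
         covariate = covariate,
         group_a = paste(group_a, collapse = "+"),
         group_b = paste(group_b, collapse = "+"),
         audit = list(audit),
         .before = 1)
}

#' Table-1-style comparison of many covariates
#'
#' Applies [compare_groups()] over a set of covariates, skipping any
#' covariate with no usable data in either group.
#'
#' @inheritParams compare_groups
#' @param covariates Character vector of covariate column names; default
#'   is the standard clinical set plus age.
#' @return Tibble with one row per comparable covariate.
#' @export
compare_all_covariates <- function(data, by, group_a, group_b,
                                   covariates = c("age", CLINICAL_LOGICAL)) {
  rows <- map(covariates, function(cv) {
    tryCatch(compare_groups(data, cv, by, group_a, group_b),
             ihcdx_validation_error = function(e) NULL)
  })
  list_rbind(keep(rows, ~ !is.null(.x)))
}
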