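# Semi-quantitative IHC scoring: H-score, staining-extent grade, and the
# TILs-weighted pSTAT3-S727 composite score.

check_profile <- function(frac0, frac1, frac2, frac3, tol = 1e-6) {
  m <- cbind(frac0, frac1, frac2, frac3)
  ok <- is.na(rowSums(m)) |
    (apply(m >= -tol & m <= 1 + tol, 1, all) & abs(rowSums(m) - 1) <= tol)
  if (!all(ok)) {
    abort("invalid staining profile: fractions must lie in [0, 1] and sum to 1",
          class = "ihcdx_validation_error")
  }
  invisible(TRUE)
}

#' H-score of a staining-intensity profile
#'
#' The H-score summarises intensity-graded staining as
#' `300 * frac3 + 200 * frac2 + 100 * frac1`, where `frac1`, `frac2`,
#' `frac3` are the fractions of cells with weak (1+), moderate (2+) and
#' strong (3+) staining. Values range over \[0, 300\].
#'
#' All arguments are vectorised; profiles must be valid (fractions in
#' \[0, 1\] summing to 1 with `frac0`, the negative fraction).
#'
#' @param frac0,frac1,frac2,frac3 Fractions of cells at intensity
#'   0/1+/2+/3+.
#' @return Numeric vector of H-scores in \[0, 300\].
#' @export
h_score <- function(frac0, frac1, frac2, frac3) {
  check_profile(frac0, frac1, frac2, frac3)
  100 * frac1 + 200 * frac2 + 300 * frac3
}

#' Fraction of positively stained cells
#'
#' @inheritParams h_score
#' @return `frac1 + frac2 + frac3`, the fraction of cells with any
#'   staining.
#' @export
positive_fraction <- function(frac0, frac1, frac2, frac3) {
  check_profile(frac0, frac1, frac2, frac3)
  frac1 + frac2 + frac3
}

#' Staining-extent grade
#'
#' Grades the fraction of positive cells into three bands: `LT30`
#' (< 30%), `MID` (30-70%, both endpoints included) and `GT70` (> 70%).
#'
#' @param pos_frac Fraction of positive cells in \[0, 1\].
#' @return Factor with levels `LT30`, `MID`, `GT70`.
#' @export
extent_grade <- function(pos_frac) {
  if (any(pos_frac < -1e-8 | pos_frac > 1 + 1e-8, na.rm = TRUE)) {
    abort("extent_grade: positive fraction outside [0, 1]",
          class = "ihcdx_validation_error")
  }
  pos_frac <- pmin(1, pmax(0, pos_frac))
  g <- dplyr::case_when(
    is.na(pos_frac) ~ NA_character_,
    pos_frac < 0.30 ~ "LT30",
    pos_frac <= 0.70 ~ "MID",
    .default = "GT70"
  )
  factor(g, levels = c("LT30", "MID", "GT70"))
}

#' TILs-weighted composite score
#'
#' Weights the H-score of a marker in tumor-infiltrating lymphocytes
#' (TILs) by the fraction of tumor area the TILs occupy:
#' `composite = H-score * tils_frac`. The score lives on the H-score
#' scale \[0, 300\], equals the TILs H-score when TILs fill the tumor
#' area, and is 0 for cases with no TILs (`tils_frac = 0`).
#'
#' A missing `tils_frac` is an error: encode "no TILs" as 0 or exclude
#' the case before scoring.
#'
#' @param tils_hscore H-score of the marker in TILs, in \[0, 300\].
#' @param tils_frac Fraction of tumor area occupied by TILs, in \[0, 1\].
#' @return Numeric composite score in \[0, 300\].
#' @export
tils_composite_score <- function(tils_hscore, tils_frac) {
  if (anyNA(tils_frac)) {
    abort(paste0("tils_composite_score: tils_frac is missing; encode 'no ",
                 "TILs' as 0 or exclude the case"),
          class = "ihcdx_validation_error")
  }
  if (any(tils_frac < 0 | tils_frac > 1)) {
    abort("tils_composite_score: tils_frac outside [0, 1]",
          class = "ihcdx_validation_error")
  }
  if (any(tils_hscore < 0 | tils_hscore > 300, na.rm = TRUE)) {
    abort("tils_composite_score: H-score outside [0, 300]",
          class = "ihcdx_validation_error")
  }
  tils_hscore * tils_frac
}

#' Score a cohort
#'
#' Appends, for every (marker, compartment) staining profile present in
#' the cohort, an H-score column `<marker>_<compartment>_hscore`, an
#' extent-grade column `<marker>_<compartment>_grade`, and — when the
#' S727 TILs profile and `tils_frac` are available — the TILs-weighted
#' composite `s727_tils_score`. Cases with `tils_frac = 0` (no TILs) get
#' a composite of 0 even without a TILs profile; cases with unknown
#' `tils_frac` get `NA`.
#'
#' @param data A cohort tibble.
#' @return The cohort with score columns appended.
#' @export
score_cohort <- function(data) {
  for (m in MARKERS) for (cp in COMPARTMENTS) {
    cols <- profile_cols(m, cp)
    if (!all(cols %in% names(data))) next
    block <- data[, cols]
    if (all(is.na(block[[1]]))) next
    hs <- h_score(block[[1]], block[[2]], block[[3]], block[[4]])
    pf <- positive_fraction(block[[1]], block[[2]], block[[3]], block[[4]])
    data[[paste0(m, "_", cp, "_hscore")]] <- hs
    data[[paste0(m, "_", cp, "_grade")]] <- extent_grade(pf)
  }
  ts_h <- data[["s727_tils_hscore"]]
  if (!is.null(ts_h) || "tils_frac" %in% names(data)) {
    tf <- data[["tils_frac"]]
    hs <- ts_h %||% rep(NA_real_, nrow(data))
    comp <- rep(NA_real_, nrow(data))
    ok <- !is.na(tf) & !is.na(hs)
    comp[ok] <- tils_composite_score(hs[ok], tf[ok])
    comp[!is.na(tf) & tf == 0] <- 0
    data$s727_tils_score <- comp
  }
  data
}
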