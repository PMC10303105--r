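# Cohort data model: wide one-row-per-case tibble, validation, file I/O,
# CD30-based subgrouping.

#' Coerce and validate a cohort table
#'
#' A cohort is a tibble with one row per case. Required columns are
#' `case_id` and `diagnosis` (one of `ALK_POS_ALCL`, `ALK_NEG_ALCL`,
#' `PTCL_NOS`); all other columns of [cohort_columns()] are optional and
#' filled with `NA` when absent. Staining profiles (four fraction columns
#' per marker/compartment) must lie in \[0, 1\] and sum to 1 within `tol`;
#' profiles within tolerance are renormalised to sum exactly to 1.
#'
#' All percentages are stored internally as fractions in \[0, 1\]. A TILs
#' fraction of 0 means "no TILs" (a real observation, distinct from `NA`
#' = unknown).
#'
#' @param data A data frame of cases.
#' @param provenance Free-text origin of the data (file path, generator
#'   config digest, ...), kept as an attribute.
#' @param tol Tolerance on profile fraction sums (default 1e-3).
#' @return A validated cohort tibble of class `ihc_cohort`.
#' @export
as_cohort <- function(data, provenance = "in-memory", tol = 1e-3) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  for (col in c("case_id", "diagnosis")) {
    if (!col %in% names(data)) {
      abort(paste0("cohort schema error: missing required column '", col, "'"),
            class = "ihcdx_schema_error")
    }
  }
  all_cols <- cohort_columns()
  for (col in setdiff(all_cols, names(data))) {
    data[[col]] <- if (col %in% c("sex")) NA_character_
    else if (col %in% c(CLINICAL_LOGICAL, "os_event")) NA
    else NA_real_
  }
  data <- data[, c(all_cols, setdiff(names(data), all_cols))]
  data$case_id <- as.character(data$case_id)
  data$diagnosis <- as.character(data$diagnosis)
  for (col in c(CLINICAL_LOGICAL, "os_event")) data[[col]] <- as.logical(data[[col]])
  num_cols <- setdiff(all_cols,
                      c("case_id", "diagnosis", "sex",
                        CLINICAL_LOGICAL, "os_event"))
  for (col in num_cols) data[[col]] <- as.numeric(data[[col]])

  if (nrow(data) > 0) {
    if (any(is.na(data$case_id) | data$case_id == "")) {
      abort("cohort validation error: empty case_id",
            class = "ihcdx_validation_error")
    }
    dup <- unique(data$case_id[duplicated(data$case_id)])
    if (length(dup) > 0) {
      abort(paste0("cohort validation error: duplicate case_id: ",
                   paste(dup, collapse = ", ")),
            class = "ihcdx_validation_error")
    }
    bad_dx <- unique(data$diagnosis[!data$diagnosis %in% DIAGNOSIS_LEVELS])
    bad_dx <- bad_dx[!is.na(bad_dx)]
    if (length(bad_dx) > 0 || anyNA(data$diagnosis)) {
      abort(paste0("cohort validation error: unknown diagnosis: ",
                   paste(bad_dx, collapse = ", ")),
            class = "ihcdx_validation_error")
    }
    for (col in c("cd30_frac", "tils_frac")) {
      v <- data[[col]]
      if (any(v < 0 | v > 1, na.rm = TRUE)) {
        abort(paste0("cohort validation error: ", col, " outside [0, 1]"),
              class = "ihcdx_validation_error")
      }
    }
    # profile blocks: all-or-none per row, in range, sum to 1 within tol
    for (m in MARKERS) for (cp in COMPARTMENTS) {
      cols <- profile_cols(m, cp)
      block <- as.matrix(data[, cols])
      n_na <- rowSums(is.na(block))
      partial <- n_na > 0 & n_na < 4
      if (any(partial)) {
        abort(paste0("cohort validation error: partial staining profile ",
                     m, "/", cp, " for case_id: ",
                     paste(data$case_id[partial], collapse = ", ")),
              class = "ihcdx_validation_error")
      }
      present <- n_na == 0
      if (any(present)) {
        if (any(block[present, ] < 0 | block[present, ] > 1)) {
          abort(paste0("cohort validation error: ", m, "/", cp,
                       " fractions outside [0, 1]"),
                class = "ihcdx_validation_error")
        }
        sums <- rowSums(block)
        off <- present & abs(sums - 1) > tol
        if (any(off)) {
          abort(paste0("cohort validation error: ", m, "/", cp,
                       " profile fractions do not sum to 1 for case_id: ",
                       paste(data$case_id[off], collapse = ", ")),
                class = "ihcdx_validation_error")
        }
        block[present, ] <- block[present, ] / sums[present]
        data[, cols] <- as_tibble(as.data.frame(block))
      }
    }
    if (any(data$os_months < 0, na.rm = TRUE)) {
      abort("cohort validation error: negative os_months",
            class = "ihcdx_validation_error")
    }
    miss_t <- !is.na(data$os_event) & is.na(data$os_months)
    if (any(miss_t)) {
      abort(paste0("cohort validation error: os_event without os_months for ",
                   "case_id: ", paste(data$case_id[miss_t], collapse = ", ")),
            class = "ihcdx_validation_error")
    }
  }
  attr(data, "provenance") <- provenance
  class(data) <- unique(c("ihc_cohort", class(data)))
  data
}

#' Read a cohort file
#'
#' Reads the wide one-row-per-case layout (see [cohort_columns()]) from a
#' CSV or TSV file and validates it. Fractions are accepted either as 0-1
#' decimals (default) or, with `percent = TRUE`, as 0-100 percentages that
#' are converted on read. The dialect is never auto-detected from values:
#' `percent` must be set explicitly.
#'
#' @param path File path.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"tsv"`.
#' @param percent If `TRUE`, fraction-valued columns in the file carry
#'   0-100 percentages.
#' @return A validated cohort tibble; provenance records the path.
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv"),
                        percent = FALSE) {
  dialect <- arg_match(dialect)
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "ihcdx_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  data <- reader(path, col_types = readr::cols(
    case_id = readr::col_character(),
    diagnosis = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE, show_col_types = FALSE)
  frac_cols <- intersect(
    c("cd30_frac", "tils_frac",
      grep("_frac[0-3]$", names(data), value = TRUE)),
    names(data)
  )
  if (percent) {
    data[frac_cols] <- lapply(data[frac_cols], function(v) v / 100)
  }
  as_cohort(data, provenance = path)
}

#' Write a cohort file
#'
#' Emits the wide layout; [read_cohort()] on the result reproduces the
#' cohort field for field (numeric fields to full double precision).
#'
#' @inheritParams read_cohort
#' @param cohort A validated cohort tibble.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("auto", "csv", "tsv"),
                         percent = FALSE) {
  dialect <- arg_match(dialect)
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "in-memory")
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  out <- as_tibble(as.data.frame(cohort[, cohort_columns()]))
  if (percent) {
    frac_cols <- c("cd30_frac", "tils_frac",
                   grep("_frac[0-3]$", names(out), value = TRUE))
    out[frac_cols] <- lapply(out[frac_cols], function(v) v * 100)
  }
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(out, path, progress = FALSE)
  invisible(path)
}

#' CD30-based subgrouping of PTCL, NOS cases
#'
#' PTCL, NOS cases with CD30 expression in at least `threshold` of tumor
#' cells are classified `CD30_HIGH`, the rest `CD30_LOW`; the rule is
#' `NOT_APPLICABLE` for ALCL cases and for PTCL, NOS without a recorded
#' CD30 fraction.
#'
#' @param diagnosis Character vector of diagnoses.
#' @param cd30_frac Numeric vector of CD30 percent-positive tumor-cell
#'   fractions in \[0, 1\].
#' @param threshold Classification threshold (default 0.80, inclusive).
#' @return Character vector: `CD30_HIGH`, `CD30_LOW` or `NOT_APPLICABLE`.
#' @export
cd30_subgroup <- function(diagnosis, cd30_frac, threshold = 0.80) {
  dplyr::case_when(
    diagnosis != "PTCL_NOS" | is.na(cd30_frac) ~ "NOT_APPLICABLE",
    cd30_frac >= threshold ~ "CD30_HIGH",
    .default = "CD30_LOW"
  )
}

#' @describeIn cd30_subgroup Data-frame interface: adds a `cd30_subgroup`
#'   column and a `subgroup` column combining diagnosis with the CD30 call
#'   (`ALK_POS_ALCL`, `ALK_NEG_ALCL`, `CD30_HIGH`, `CD30_LOW`, or
#'   `PTCL_NOS` when the CD30 fraction is unknown).
#' @param data A cohort tibble.
#' @export
classify_cd30_subgroup <- function(data, threshold = 0.80) {
  data %>%
    mutate(
      cd30_subgroup = cd30_subgroup(.data$diagnosis, .data$cd30_frac, threshold),
      subgroup = if_else(.data$cd30_subgroup == "NOT_APPLICABLE",
                         .data$diagnosis, .data$cd30_subgroup)
    )
}

#' Subgroup counts of a cohort
#'
#' Counts cases by diagnosis and, within PTCL, NOS, by CD30 subgroup.
#'
#' @param data A cohort tibble.
#' @param threshold CD30-high threshold passed to [cd30_subgroup()].
#' @return A tibble with columns `subgroup` and `n`, one row per level of
#'   `ALK_POS_ALCL`, `ALK_NEG_ALCL`, `PTCL_NOS`, `CD30_HIGH`, `CD30_LOW`
#'   (PTCL, NOS counts all PTCL, NOS cases; CD30 rows partition those with
#'   a recorded CD30 fraction).
#' @export
subgroup_counts <- function(data, threshold = 0.80) {
  sg <- cd30_subgroup(data$diagnosis, data$cd30_frac, threshold)
  lv <- c(DIAGNOSIS_LEVELS, "CD30_HIGH", "CD30_LOW")
  n <- c(
    sum(data$diagnosis == "ALK_POS_ALCL"),
    sum(data$diagnosis == "ALK_NEG_ALCL"),
    sum(data$diagnosis == "PTCL_NOS"),
    sum(sg == "CD30_HIGH"),
    sum(sg == "CD30_LOW")
  )
  tibble(subgroup = lv, n = as.integer(n))
}
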