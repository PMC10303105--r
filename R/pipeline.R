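# End-to-end workflow: score -> classify -> compare -> survival, with
# machine-readable TSV/JSON reports that echo their audited inputs.

#' Pipeline configuration
#'
#' @param input Path to a cohort file, or `NULL` to simulate.
#' @param sim_config A `cohort_config` used when `input` is `NULL`.
#' @param markers Markers entering the diagnostic evaluation.
#' @param cd30_high_threshold CD30-high classification threshold in
#'   \[0, 1\].
#' @param positive_class,negative_class Subgroups defining the
#'   diagnostic contrast (positive = disease the classifier calls).
#' @param cutoffs Optional named numeric vector of fixed per-marker
#'   cutoffs; markers not named fall back to their own Youden-optimal
#'   cutoff.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for simulation.
#' @param percent Whether `input` carries 0-100 percentages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim_config = default_study_config(),
                            markers = c("y705", "s727", "cd30"),
                            cd30_high_threshold = 0.8,
                            positive_class = "ALK_NEG_ALCL",
                            negative_class = "CD30_HIGH",
                            cutoffs = NULL, out_dir = tempfile("ihcdx_"),
                            seed = 1, percent = FALSE) {
  unknown <- setdiff(markers, MARKERS)
  if (length(unknown) > 0) {
    abort(paste0("pipeline_config: unknown marker(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ihcdx_config_error")
  }
  stopifnot(cd30_high_threshold >= 0, cd30_high_threshold <= 1)
  if (!is.null(cutoffs)) {
    stopifnot(is.numeric(cutoffs), !is.null(names(cutoffs)),
              all(names(cutoffs) %in% markers),
              all(cutoffs >= 0 & cutoffs <= 300))
  }
  structure(
    list(input = input, sim_config = sim_config, markers = markers,
         cd30_high_threshold = cd30_high_threshold,
         positive_class = positive_class, negative_class = negative_class,
         cutoffs = cutoffs, out_dir = out_dir, seed = seed,
         percent = percent),
    class = "pipeline_config"
  )
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Diagnostic marker panel evaluation
#'
#' Per-marker ROC analysis with Youden-optimal (or supplied) cutoffs,
#' parallel/serial combination of the Y705 and S727 calls, and pairwise
#' DeLong AUC comparisons, on one two-class contrast of a scored,
#' subgrouped cohort.
#'
#' @inheritParams roc_from_cohort
#' @param markers Markers to evaluate (tumor-compartment H-scores).
#' @param cutoffs Optional named fixed cutoffs (see
#'   [pipeline_config()]).
#' @return List with `rocs` (named `ihc_roc` list), `evaluations`
#'   (tibble: one row per marker and per combination), `auc_comparisons`
#'   (tibble of pairwise DeLong tests).
#' @export
diagnostic_panel <- function(data, markers = c("y705", "s727", "cd30"),
                             class_col = "subgroup",
                             positive_class = "ALK_NEG_ALCL",
                             negative_class = "CD30_HIGH",
                             cutoffs = NULL) {
  score_cols <- paste0(markers, "_tumor_hscore")
  missing_cols <- score_cols[!score_cols %in% names(data)]
  if (length(missing_cols) > 0) {
    abort(paste0("diagnostic_panel: missing score column(s): ",
                 paste(missing_cols, collapse = ", "),
                 " (run score_cohort() first)"),
          class = "ihcdx_schema_error")
  }
  keep <- data[[class_col]] %in% c(positive_class, negative_class)
  sub <- data[keep, ]
  labels <- sub[[class_col]] == positive_class
  rocs <- setNames(map(markers, function(m) {
    empirical_roc(sub[[paste0(m, "_tumor_hscore")]], labels,
                  positive_label = positive_class)
  }), markers)
  evals <- list_rbind(map(markers, function(m) {
    roc <- rocs[[m]]
    fixed <- cutoffs[m]
    ev <- if (!is.null(cutoffs) && !is.na(fixed)) {
      mutate(evaluate_at_cutoff(roc$scores, roc$labels, unname(fixed)),
             degenerate = FALSE)
    } else {
      youden_optimal_cutoff(roc)
    }
    mutate(ev, marker = m, auc = roc$auc, .before = 1)
  }))
  calls <- setNames(map(markers, function(m) {
    cut <- evals$cutoff[evals$marker == m]
    sub[[paste0(m, "_tumor_hscore")]] >= cut
  }), markers)
  combos <- NULL
  if (all(c("y705", "s727") %in% markers)) {
    pair <- calls[c("y705", "s727")]
    combos <- bind_rows(
      combine_markers(pair, labels, "parallel"),
      combine_markers(pair, labels, "serial")
    )
  }
  pairs <- if (length(markers) >= 2) combn(markers, 2, simplify = FALSE) else list()
  aucs <- list_rbind(map(pairs, function(p) {
    mutate(delong_paired_test(sub[[paste0(p[1], "_tumor_hscore")]],
                              sub[[paste0(p[2], "_tumor_hscore")]],
                              labels),
           marker_a = p[1], marker_b = p[2], .before = 1)
  }))
  list(rocs = rocs, evaluations = evals, combinations = combos,
       auc_comparisons = aucs)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a cohort, scores it, classifies CD30 subgroups,
#' evaluates the diagnostic marker panel, compares clinical covariates
#' between the contrast groups, and runs the survival analyses (by
#' diagnosis and by TILs-score stratification). All results are written
#' under `config$out_dir` as TSV/JSON; every JSON report embeds the
#' configuration hash and seed, so reruns with an identical
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, panel, comparisons and
#'   survival results plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (is.null(config$input)) {
    generate_cohort(config$sim_config, config$seed)
  } else {
    read_cohort(config$input, percent = config$percent)
  }
  scored <- cohort %>%
    score_cohort() %>%
    classify_cd30_subgroup(threshold = config$cd30_high_threshold)
  readr::write_tsv(as_tibble(as.data.frame(scored)),
                   file.path(config$out_dir, "scored_cohort.tsv"),
                   progress = FALSE)
  # hash everything but the output location, so reruns into different
  # directories produce byte-identical reports
  meta <- list(
    config_hash = hash(unclass(config)[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    provenance = attr(cohort, "provenance")
  )

  panel <- diagnostic_panel(
    scored, markers = config$markers,
    positive_class = config$positive_class,
    negative_class = config$negative_class,
    cutoffs = config$cutoffs
  )
  walk(names(panel$rocs), function(m) {
    readr::write_tsv(panel$rocs[[m]]$points,
                     file.path(config$out_dir, paste0("roc_", m, ".tsv")),
                     progress = FALSE)
  })
  write_report_json(
    c(meta, list(
      positive_class = config$positive_class,
      negative_class = config$negative_class,
      markers = as.list(setNames(
        map(config$markers, function(m) {
          ev <- panel$evaluations[panel$evaluations$marker == m, ]
          list(auc = panel$rocs[[m]]$auc, cutoff = ev$cutoff,
               sensitivity = ev$sensitivity, specificity = ev$specificity,
               youden = ev$youden,
               confusion = list(tp = ev$tp, fp = ev$fp, tn = ev$tn,
                                fn = ev$fn))
        }), config$markers)),
      combinations = panel$combinations,
      auc_comparisons = panel$auc_comparisons
    )),
    file.path(config$out_dir, "diagnostics.json")
  )

  comparisons <- compare_all_covariates(
    scored, by = "subgroup",
    group_a = config$positive_class, group_b = config$negative_class
  )
  readr::write_tsv(select(comparisons, -"audit"),
                   file.path(config$out_dir, "comparisons.tsv"),
                   progress = FALSE)

  surv_dx <- survival_by_group(scored, "diagnosis")
  strat <- stratify_by_tils_score(scored)
  surv_tils <- tryCatch(survival_by_group(strat, "tils_group"),
                        ihcdx_validation_error = function(e) NULL)
  walk(names(surv_dx$curves), function(g) {
    readr::write_tsv(surv_dx$curves[[g]]$steps,
                     file.path(config$out_dir, paste0("km_", g, ".tsv")),
                     progress = FALSE)
  })
  write_report_json(
    c(meta, list(
      by_diagnosis = list(summary = surv_dx$summary,
                          logrank = surv_dx$logrank),
      tils_stratification = list(
        split_value = tils_split_value(strat),
        counts = as.list(table(strat$tils_group)),
        summary = if (!is.null(surv_tils)) surv_tils$summary,
        logrank = if (!is.null(surv_tils)) surv_tils$logrank
      )
    )),
    file.path(config$out_dir, "survival.json")
  )

  invisible(list(cohort = scored, panel = panel, comparisons = comparisons,
                 survival_by_diagnosis = surv_dx,
                 tils_stratification = strat,
                 survival_by_tils = surv_tils,
                 out_dir = config$out_dir, meta = meta))
}
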