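# Empirical ROC analysis: curve construction, Youden-optimal cutoff
# selection, fixed-cutoff evaluation, parallel/serial marker combination,
# and the DeLong paired-AUC comparison.

drop_incomplete <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  list(scores = scores[keep], labels = as.logical(labels[keep]))
}

confusion_at <- function(scores, labels, cutoff, ge = TRUE) {
  call_pos <- if (ge) scores >= cutoff else scores > cutoff
  c(tp = sum(call_pos & labels), fp = sum(call_pos & !labels),
    tn = sum(!call_pos & !labels), fn = sum(!call_pos & labels))
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' truth. Candidate cutoffs are the midpoints between adjacent distinct
#' observed scores plus sentinels at plus/minus infinity; a case is called
#' positive when its score is at or above the cutoff. The AUC is the
#' tie-aware pair-counting statistic: the fraction of
#' (positive, negative) pairs the score orders correctly, counting ties
#' as one half.
#'
#' @param scores Numeric score vector.
#' @param labels Logical vector (`TRUE` = positive class), same length;
#'   pairs with a missing score or label are dropped.
#' @param positive_label Free-text description of what `TRUE` means
#'   (e.g. `"ALK_NEG_ALCL"`), recorded so the orientation of the curve is
#'   explicit.
#' @return An object of class `ihc_roc`: a list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn` in
#'   descending threshold order), `auc`, `n_pos`, `n_neg`,
#'   `positive_label`, and the retained `scores`/`labels`.
#' @export
empirical_roc <- function(scores, labels, positive_label = "positive") {
  d <- drop_incomplete(scores, labels)
  scores <- d$scores; labels <- d$labels
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("empirical_roc: ROC undefined with a single class present",
          class = "ihcdx_degenerate_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  s <- sort(unique(scores))
  thr <- c(Inf, if (length(s) > 1) rev((s[-1] + s[-length(s)]) / 2), -Inf)
  pts <- map(thr, function(t) as.list(confusion_at(scores, labels, t)))
  pts <- list_rbind(map(pts, as_tibble))
  pts <- mutate(pts,
                threshold = thr,
                sensitivity = .data$tp / n_pos,
                specificity = .data$tn / n_neg,
                .before = 1)
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
         positive_label = positive_label, scores = scores, labels = labels),
    class = "ihc_roc"
  )
}

#' @export
print.ihc_roc <- function(x, ...) {
  cat("Empirical ROC curve (positive class: ", x$positive_label, ")\n",
      "  n = ", x$n_pos, " positive / ", x$n_neg, " negative\n",
      "  AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ihc_roc <- function(x, ...) x$points

#' @export
glance.ihc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         positive_label = x$positive_label)
}

#' ROC curve from a cohort table
#'
#' Convenience wrapper: builds an [empirical_roc()] from a score column
#' and a two-class grouping column of a (scored) cohort tibble.
#'
#' @param data A cohort tibble, typically after [score_cohort()] and
#'   [classify_cd30_subgroup()].
#' @param score Name of the score column (string).
#' @param class_col Name of the grouping column (default `"subgroup"`).
#' @param positive_class,negative_class Values of `class_col` defining
#'   the two classes; other rows are dropped.
#' @return An `ihc_roc` object.
#' @export
roc_from_cohort <- function(data, score, class_col = "subgroup",
                            positive_class = "ALK_NEG_ALCL",
                            negative_class = "CD30_HIGH") {
  keep <- data[[class_col]] %in% c(positive_class, negative_class)
  empirical_roc(data[[score]][keep],
                data[[class_col]][keep] == positive_class,
                positive_label = positive_class)
}

#' Evaluate a score at a fixed cutoff
#'
#' A case is called positive when its score is at or above the cutoff
#' (set `ge = FALSE` for a strict-greater convention). Returns confusion
#' counts, sensitivity, specificity and the Youden index
#' (sensitivity + specificity - 1).
#'
#' @inheritParams empirical_roc
#' @param cutoff Finite cutoff on the score scale.
#' @param ge Call positive at `score >= cutoff` (default) or
#'   `score > cutoff`.
#' @return One-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
evaluate_at_cutoff <- function(scores, labels, cutoff, ge = TRUE) {
  stopifnot(is.finite(cutoff))
  d <- drop_incomplete(scores, labels)
  cc <- confusion_at(d$scores, d$labels, cutoff, ge)
  sens <- cc["tp"] / (cc["tp"] + cc["fn"])
  spec <- cc["tn"] / (cc["tn"] + cc["fp"])
  tibble(cutoff = cutoff, tp = cc[["tp"]], fp = cc[["fp"]],
         tn = cc[["tn"]], fn = cc[["fn"]],
         sensitivity = unname(sens), specificity = unname(spec),
         youden = unname(sens + spec - 1))
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Scans every enumerated threshold of the curve and returns the
#' evaluation at the cutoff maximising the Youden index. Ties are broken
#' towards higher specificity, then towards the larger cutoff. Infinite
#' sentinel thresholds are reported as the midpoint convention cannot
#' apply there only when they win outright (degenerate data); with a
#' single distinct score the curve has no informative cutoff and the
#' result is flagged degenerate.
#'
#' @param roc An `ihc_roc` object.
#' @return One-row tibble as [evaluate_at_cutoff()], plus a `degenerate`
#'   flag (`TRUE` when no cutoff discriminates, i.e. max Youden index 0).
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ihc_roc"))
  pts <- roc$points %>%
    mutate(youden = .data$sensitivity + .data$specificity - 1) %>%
    arrange(desc(.data$youden), desc(.data$specificity), desc(.data$threshold))
  best <- pts[1, ]
  tibble(cutoff = best$threshold, tp = best$tp, fp = best$fp,
         tn = best$tn, fn = best$fn, sensitivity = best$sensitivity,
         specificity = best$specificity, youden = best$youden,
         degenerate = best$youden <= 0)
}

#' Combine dichotomised marker calls
#'
#' `parallel` combination (logical OR) calls a case positive when any
#' component marker is positive and can only increase sensitivity;
#' `serial` combination (logical AND) requires all markers positive and
#' can only increase specificity.
#'
#' @param calls Named list of logical call vectors, one per marker, all
#'   the same length and case order.
#' @param mode `"parallel"` (OR) or `"serial"` (AND).
#' @return Logical vector of combined calls.
#' @export
combine_calls <- function(calls, mode = c("parallel", "serial")) {
  mode <- arg_match(mode)
  stopifnot(is.list(calls), length(calls) >= 1)
  len <- lengths(calls)
  if (length(unique(len)) != 1) {
    abort("combine_calls: call vectors differ in length",
          class = "ihcdx_validation_error")
  }
  m <- do.call(cbind, lapply(calls, as.logical))
  if (mode == "parallel") rowSums(m) > 0 else rowSums(m) == ncol(m)
}

#' @describeIn combine_calls Evaluate a combined rule against truth
#'   labels; returns the same columns as [evaluate_at_cutoff()] with the
#'   combination descriptor in a `rule` column.
#' @param labels Logical truth vector.
#' @export
combine_markers <- function(calls, labels, mode = c("parallel", "serial")) {
  mode <- arg_match(mode)
  comb <- combine_calls(calls, mode)
  if (length(comb) != length(labels)) {
    abort("combine_markers: labels length mismatch",
          class = "ihcdx_validation_error")
  }
  labels <- as.logical(labels)
  cc <- c(tp = sum(comb & labels), fp = sum(comb & !labels),
          tn = sum(!comb & !labels), fn = sum(!comb & labels))
  sens <- cc[["tp"]] / (cc[["tp"]] + cc[["fn"]])
  spec <- cc[["tn"]] / (cc[["tn"]] + cc[["fp"]])
  op <- if (mode == "parallel") "|" else "&"
  tibble(rule = paste(names(calls) %||% seq_along(calls), collapse = op),
         mode = mode, tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]],
         fn = cc[["fn"]], sensitivity = sens, specificity = spec,
         youden = sens + spec - 1)
}

# DeLong structural components: for each positive i, the mean of the
# Mann-Whitney kernel against all negatives (and vice versa).
delong_components <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same cases using the
#' DeLong structural-components estimator of the variance of the AUC
#' difference for paired designs, with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Numeric score vectors on identical cases.
#' @param labels Logical truth vector (`TRUE` = positive class).
#' @return One-row tibble: `auc_a`, `auc_b`, `delta` (a minus b), `z`,
#'   `p_value`, `method`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]
  labels <- as.logical(labels[keep])
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) {
    abort("delong_paired_test: both classes must be present",
          class = "ihcdx_degenerate_error")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= 0) {
    if (abs(delta) > 1e-12) {
      abort("delong_paired_test: zero variance estimate with unequal AUCs",
            class = "ihcdx_degenerate_error")
    }
    z <- 0
  } else {
    z <- delta / sqrt(var_delta)
  }
  tibble(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
         p_value = min(1, 2 * pnorm(-abs(z))),
         method = "DeLong paired AUC comparison")
}
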