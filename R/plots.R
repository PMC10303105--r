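# ggplot2 methods for the result objects.

#' @export
autoplot.ihc_roc <- function(object, ...) {
  pts <- arrange(object$points, .data$sensitivity, desc(.data$specificity))
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = paste0("ROC: ", object$positive_label,
                     " (AUC = ", format(object$auc, digits = 3), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ihc_km <- function(object, ...) {
  steps <- object$steps
  df <- bind_rows(tibble(time = 0, survival = 1),
                  select(steps, "time", "survival"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(
      data = filter(steps, .data$n_censor > 0),
      ggplot2::aes(x = .data$time, y = .data$survival),
      shape = 3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for several groups
#'
#' @param curves Named list of `ihc_km` objects (e.g. the `curves`
#'   element of [survival_by_group()]).
#' @return A ggplot object.
#' @export
plot_km_groups <- function(curves) {
  df <- list_rbind(imap(curves, function(km, g) {
    bind_rows(tibble(time = 0, survival = 1),
              select(km$steps, "time", "survival")) %>%
      mutate(group = g)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}
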