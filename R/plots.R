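# ggplot2 graphics for recordings, screening results, the RFE curve and
# performance summaries.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic 5xSTS recording
#'
#' Faceted time series of the three segment-pitch channels and the
#' vertical displacement.
#'
#' @param object An `sts_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sts_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data, -"time_s",
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = sprintf("5xSTS recording %s", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Plot per-feature screening results
#'
#' -log10 p-value per feature, colored by significance, with the alpha
#' level as a dashed reference line.
#'
#' @param object A `frailty_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frailty_screen <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$feature,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#00688B", `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Two-group feature screening") +
    ggplot2::theme_minimal()
}

#' Plot the subset-AUC curve of an RFE ranking
#'
#' Mean validation AUC of the top-k ranked feature subsets against k, with
#' the selection AUC threshold as a dashed line.
#'
#' @param object A `frailty_rfe`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frailty_rfe <- function(object, ...) {
  rk <- object$ranking
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$rank, y = .data$subset_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$phenotype), size = 2.5) +
    ggplot2::geom_hline(yintercept = object$config$auc_threshold,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = rk$rank) +
    ggplot2::labs(x = "Number of top-ranked features (k)",
                  y = "Mean validation AUC",
                  title = "Model performance vs. feature-subset size") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap performance summary
#'
#' Metric means with their 95% confidence intervals.
#'
#' @param object A `frailty_performance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frailty_performance <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Percent",
                  title = "Bootstrap validation performance (mean and 95% CI)") +
    ggplot2::theme_minimal()
}

#' Group distributions of selected features
#'
#' Boxplots of feature values by frailty status, faceted per feature.
#'
#' @param table Feature table with binary `status`.
#' @param features Features to plot (default: all feature columns).
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(table, features = NULL) {
  if (is.null(features)) features <- .feature_columns(table)
  long <- tidyr::pivot_longer(table[, c("status", features)], -"status",
                              names_to = "feature", values_to = "value")
  long$group <- factor(long$status, c(0, 1), c("robust", "pre-frail/frail"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
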