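#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_abline
#'   scale_fill_viridis_c labs theme_minimal facet_wrap coord_equal
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

image_to_long <- function(img) {
  m <- unclass(as.matrix(img))
  tibble::tibble(
    stat = factor(rep(rownames(m), times = ncol(m)), levels = rev(stat_names())),
    window = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
}

#' Heatmap of a feature image
#'
#' Statistics on rows, subwindows on columns — the image the classifier
#' sees. Values can be capped for display (spatially concentrated rows
#' otherwise dominate the color scale).
#'
#' @param object a `feature_image` (or `stat_profile`).
#' @param cap upper display cap for the fill scale (default 0.25; `NULL`
#'   disables).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.feature_image <- function(object, cap = 0.25, ...) {
  df <- image_to_long(object)
  if (!is.null(cap)) df$value <- pmin(df$value, cap)
  ggplot(df, aes(x = .data$window, y = .data$stat, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = "share") +
    labs(x = "subwindow", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.stat_profile <- function(object, cap = NULL, ...) {
  autoplot.feature_image(object, cap = cap, ...)
}

#' Average feature image per class
#'
#' Averages the feature columns of a labeled feature table within each class
#' and displays the mean images side by side — the average-case view of what
#' distinguishes the five classes.
#'
#' @param features labeled feature tibble (e.g. [build_training_set()]).
#' @param cap display cap for the fill scale.
#' @return A ggplot faceted by class.
#' @export
plot_mean_images <- function(features, cap = 0.25) {
  fc <- feature_cols(features)
  df <- features |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fc), mean), .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(fc), names_to = "feature", values_to = "value") |>
    tidyr::separate_wider_regex("feature", c(stat = ".*", "_win", window = "[0-9]+")) |>
    dplyr::mutate(stat = factor(.data$stat, levels = rev(stat_names())),
                  window = as.integer(.data$window),
                  value = if (is.null(cap)) .data$value else pmin(.data$value, cap))
  ggplot(df, aes(x = .data$window, y = .data$stat, fill = .data$value)) +
    geom_tile() +
    facet_wrap(~label, nrow = 1) +
    scale_fill_viridis_c(name = "share") +
    labs(x = "subwindow", y = NULL) +
    theme_minimal()
}

#' Confusion heatmap and ROC curve for an evaluation
#'
#' @param object a `sweep_eval`.
#' @param type "confusion" or "roc".
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sweep_eval <- function(object, type = c("confusion", "roc"), ...) {
  type <- match.arg(type)
  if (type == "confusion") {
    df <- tidy(object)
    ggplot(df, aes(x = .data$pred, y = .data$truth, fill = .data$fraction)) +
      geom_tile() +
      scale_fill_viridis_c(limits = c(0, 1)) +
      labs(x = "predicted class", y = "true class") +
      coord_equal() +
      theme_minimal()
  } else {
    ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
      geom_line() +
      geom_abline(linetype = "dashed", color = "grey60") +
      labs(x = "false positive rate", y = "true positive rate",
           subtitle = sprintf("sweep vs. unselected AUC = %.3f", object$auc)) +
      theme_minimal()
  }
}

#' Training history curves
#'
#' @param object a trained `sweep_cnn`.
#' @param ... unused.
#' @return A ggplot of validation accuracy by epoch.
#' @export
autoplot.sweep_cnn <- function(object, ...) {
  h <- tidy(object)
  if (!nrow(h)) stop("model has no training history")
  ggplot(h, aes(x = .data$epoch, y = .data$val_accuracy)) +
    geom_line() +
    labs(x = "epoch", y = "validation accuracy") +
    theme_minimal()
}
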