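# ggplot2 visualisations for the result types.

#' @export
autoplot.similarity_table <- function(object, layer = "hog_similarity", ...) {
  xcol <- if ("group_pair" %in% names(object)) "group_pair" else "activity_low"
  ycol <- if ("group_pair" %in% names(object)) "activity" else "activity_mid"
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[xcol]], y = .data[[ycol]],
    fill = .data[[layer]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.na(.data[[layer]]), "N/A", sprintf("%.2f", .data[[layer]])
    )), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = layer) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cstt_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "epoch", y = "training cross-entropy",
      title = paste("mode:", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param roc Result of [roc_auc_ovr()].
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(roc) {
  ggplot2::ggplot(roc$curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      subtitle = sprintf(
        "micro AUC %.2f, macro AUC %.2f",
        roc$micro_auc, roc$macro_auc
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative-gain curves
#'
#' @param gains Named list of [cumulative_gain()] tibbles (as in an
#'   `eval_report`).
#' @return A ggplot object.
#' @export
plot_cumulative_gains <- function(gains) {
  df <- dplyr::bind_rows(purrr::compact(gains), .id = "class")
  ggplot2::ggplot(df, ggplot2::aes(
    .data$fraction_inspected, .data$gain,
    colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "fraction of samples inspected", y = "fraction of positives captured") +
    ggplot2::theme_minimal()
}

#' Plot a normalized confusion matrix
#'
#' @param cm One matrix from [confusion_by_group()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm, title = NULL) {
  df <- as_tibble(as.table(cm), .name_repair = ~ c("true", "predicted", "rate"))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = title, x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
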