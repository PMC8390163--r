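#' Accuracy-versus-epoch curve of a fit
#'
#' Plots the per-epoch training (and, when recorded, held-out) accuracy
#' trace of a single training run.
#'
#' @param object An `mspnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mspnet_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace,
                            cols = c("train_acc", "eval_acc"),
                            names_to = "set", values_to = "accuracy")
  tr <- dplyr::filter(tr, is.finite(.data$accuracy))
  tr$set <- factor(tr$set, levels = c("train_acc", "eval_acc"),
                   labels = c("training", "held-out"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' Renders a confusion matrix as a tile plot with per-true-class rates,
#' the usual presentation of multiclass classifier results.
#'
#' @param object A `plaque_cm` confusion matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plaque_cm <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "count"))
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$truth),
    rate = ifelse(sum(.data$count) > 0, .data$count / sum(.data$count), 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.3f)", .data$count, .data$rate)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "rate") +
    ggplot2::theme_minimal()
}

#' Cross-validation accuracy curves
#'
#' Overlays the per-fold held-out accuracy traces of a cross-validation
#' run.
#'
#' @param object An `mspnet_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mspnet_cv <- function(object, ...) {
  traces <- purrr::imap_dfr(object$fits, function(fit, f) {
    dplyr::mutate(fit$trace, fold = factor(f))
  })
  traces <- dplyr::filter(traces, is.finite(.data$eval_acc))
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$epoch, y = .data$eval_acc,
                                       colour = .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "held-out accuracy", colour = "fold") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
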