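# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted CMPNN
#'
#' @param x a `cmpnn_model`.
#' @param ... unused.
#' @return a tibble with one row per parameter block: name, shape, number
#'   of values.
#' @export
tidy.cmpnn_model <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    rows = vapply(x$params, NROW, 0L),
    cols = vapply(x$params, function(p) if (is.matrix(p)) ncol(p) else 1L, 0L),
    n_values = vapply(x$params, length, 0L)
  )
}

#' @rdname tidy.cmpnn_model
#' @export
glance.cmpnn_model <- function(x, ...) {
  tibble::tibble(
    hidden_size = x$config$hidden_size, depth = x$config$depth,
    n_parameters = sum(vapply(x$params, length, 0L)),
    epochs_trained = max(x$log$epoch), best_epoch = x$best_epoch,
    best_val_auc = x$best_val_auc,
    n_train = x$n_train, n_validation = x$n_validation
  )
}

#' @rdname tidy.cmpnn_model
#' @param object a `cmpnn_model` (for `autoplot`).
#' @return `autoplot` returns a ggplot of training loss, validation AUC and
#'   learning rate against epoch.
#' @export
autoplot.cmpnn_model <- function(object, ...) {
  df <- object$log |>
    tidyr::pivot_longer(c("train_loss", "val_auc", "lr"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "CMPNN training trajectory") +
    ggplot2::theme_minimal()
}

#' Tidy a metric report
#'
#' @param x a `metric_report` from [evaluate_predictions()].
#' @param ... unused.
#' @return `tidy`: a two-column tibble (metric, value); `glance`: the
#'   metrics as one wide row.
#' @export
tidy.metric_report <- function(x, ...) {
  tibble::tibble(metric = metric_names,
                 value = unlist(x[metric_names], use.names = FALSE))
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::as_tibble(x[metric_names]) |>
    dplyr::mutate(n = x$n, threshold = x$threshold)
}

#' @rdname tidy.metric_report
#' @param object a `metric_report` (for `autoplot`).
#' @return `autoplot` returns the ROC curve as a ggplot.
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Descriptor distributions by toxicity class
#'
#' Box plots of the six physicochemical descriptors split by class,
#' mirroring the usual toxicant-vs-non-toxicant comparison.
#'
#' @param data a compound tibble with `label` and descriptor columns
#'   ([compute_descriptors()] is called if they are missing).
#' @return a ggplot.
#' @export
plot_descriptors <- function(data) {
  desc_cols <- c("weight", "tpsa", "logp", "hbd", "hba", "rot_bonds")
  if (!all(desc_cols %in% names(data))) data <- compute_descriptors(data)
  df <- data |>
    dplyr::mutate(class = factor(.data$label, c(0, 1),
                                 c("non-toxic", "toxic"))) |>
    tidyr::pivot_longer(dplyr::all_of(desc_cols), names_to = "descriptor",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Physicochemical descriptors by toxicity class") +
    ggplot2::theme_minimal()
}
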