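# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a CNN
#'
#' @param x A `multicnn_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch, train_loss, val_loss,
#'   val_metric`.
#' @method tidy multicnn_model
#' @export
tidy.multicnn_model <- function(x, ...) x$history

#' One-row summary of a trained CNN
#'
#' @param x A `multicnn_model`.
#' @param ... Unused.
#' @method glance multicnn_model
#' @export
glance.multicnn_model <- function(x, ...) {
  h <- x$history
  best <- h[h$epoch == x$best_epoch, ]
  tibble::tibble(task = x$spec$task, n_branches = length(x$input_shapes),
                 n_epochs = nrow(h), best_epoch = x$best_epoch,
                 train_loss = best$train_loss, val_loss = best$val_loss,
                 val_metric = best$val_metric, seed = x$seed)
}

#' Tidy a baseline model into its importance scores
#'
#' @param x A `trained_baseline`.
#' @param d The `flat_dataset` (required for SVM permutation importance).
#' @param ... Passed to [baseline_importance()].
#' @return Tibble: `name, layer, feature, channel, score`.
#' @method tidy trained_baseline
#' @export
tidy.trained_baseline <- function(x, d = NULL, ...) {
  imp <- baseline_importance(x, d, ...)
  out <- x$feature_map
  out$score <- unname(imp[out$name])
  tibble::as_tibble(out)
}

#' Tidy a tuning run into its trial history
#'
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @method tidy tuning_result
#' @export
tidy.tuning_result <- function(x, ...) x$trials

#' One-row summary of a tuning run
#'
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @method glance tuning_result
#' @export
glance.tuning_result <- function(x, ...)
  tibble::tibble(n_trials = nrow(x$trials),
                 n_failed = sum(is.na(x$trials$value)),
                 best_value = x$best_value, best_trial = x$best_trial,
                 seed = x$seed)

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...)
  tibble::tibble(model = attr(x, "model"), metric = attr(x, "metric"),
                 mean = attr(x, "mean"), sd = attr(x, "sd"), k = nrow(x))

#' Plot a CNN training history
#'
#' @param object A `multicnn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot multicnn_model
#' @export
autoplot.multicnn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$fold),
                                       y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mean"), linetype = 2) +
    ggplot2::labs(x = "fold", y = attr(object, "metric"),
                  title = sprintf("%s: mean %s = %.3f", attr(object, "model"),
                                  attr(object, "metric"),
                                  attr(object, "mean"))) +
    ggplot2::theme_minimal()
}

#' Plot a tuning optimisation history
#'
#' Trial objective values with the running best overlaid.
#'
#' @param object A `tuning_result`.
#' @param ... Unused.
#' @method autoplot tuning_result
#' @export
autoplot.tuning_result <- function(object, ...) {
  b <- best_so_far(object)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far),
                       colour = "firebrick") +
    ggplot2::labs(x = "trial", y = "objective") +
    ggplot2::theme_minimal()
}

#' Dot plot of the top enriched pathways
#'
#' @param object An `enrichment_result`.
#' @param n How many pathways to show.
#' @param ... Unused.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n = 10, ...) {
  top <- top_pathways(object, n = n)
  top$set <- factor(top$set, levels = rev(top$set))
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$p_value), y = .data$set,
                                    size = .data$overlap,
                                    colour = .data$p_adjust)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  size = "overlap", colour = "adj. p") +
    ggplot2::theme_minimal()
}

#' Lollipop plot of the top-ranked markers
#'
#' @param object A `marker_report`.
#' @param k How many markers to show.
#' @param ... Unused.
#' @method autoplot marker_report
#' @export
autoplot.marker_report <- function(object, k = 20, ...) {
  top <- top_markers(object, k = k)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$saliency, y = .data$feature,
                                    colour = .data$layer)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "saliency", y = NULL) +
    ggplot2::theme_minimal()
}

roc_points <- function(labels, scores) {
  y <- binarize_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & y == 0) / sum(y == 0),
      tpr = sum(pred & y == 1) / sum(y == 1))
  }, c(fpr = 0, tpr = 0))
  tibble::tibble(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
}

#' ROC and precision-recall curve plots
#'
#' @param labels Binary labels.
#' @param scores Real-valued scores.
#' @return A ggplot.
#' @export
plot_roc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", roc_auc(labels, scores))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @export
plot_pr <- function(labels, scores) {
  pts <- pr_curve(labels, scores)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}
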