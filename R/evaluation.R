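# Metrics: ROC AUC (rank / Mann-Whitney formulation), precision-recall curve,
# Pearson correlation, R squared, and cross-validated evaluation reports.

# Coerce labels to 0/1 with 1 = positive class (TRUE, 1, or the second of the
# two sorted unique values).
binarize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (length(u) != 2)
    stop("need exactly 2 classes, got ", length(u), call. = FALSE)
  as.integer(labels == u[2])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation, equivalent to the trapezoidal area
#' over unique score thresholds; ties in the scores are handled by average
#' ranks, so the result is deterministic.
#'
#' @param labels Binary labels (logical, 0/1, or any two-level vector; the
#'   second sorted level is the positive class).
#' @param scores Real-valued scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- binarize_labels(labels)
  if (length(y) != length(scores))
    stop("labels and scores differ in length", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve
#'
#' One point per unique score threshold (predict positive when
#' `score >= threshold`), ordered by increasing recall, with the recall-0
#' endpoint carrying the precision of the highest threshold (step convention).
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(labels, scores) {
  y <- binarize_labels(labels)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y))
    stop("both classes must be present for a PR curve", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    c(recall = tp / n1, precision = tp / sum(pred))
  }, c(recall = 0, precision = 0))
  tibble::tibble(threshold = c(Inf, thr),
                 recall = unname(c(0, pts["recall", ])),
                 precision = unname(c(pts["precision", 1],
                                      pts["precision", ])))
}

#' Pearson correlation coefficient
#'
#' @param y_true Observed values (non-constant, length >= 2).
#' @param y_pred Predicted values.
#' @return PCC in \[-1, 1\].
#' @export
pcc <- function(y_true, y_pred) {
  if (length(y_true) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(y_true) == 0)
    stop("y_true is constant; correlation undefined", call. = FALSE)
  stats::cor(y_true, y_pred)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`; a constant prediction at the mean scores 0,
#' and predictions worse than the mean score negative.
#'
#' @inheritParams pcc
#' @return R squared (<= 1).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) < 2) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true is constant; R squared undefined", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# Fit the requested model on the training portion and score the held-out
# portion; shared by evaluate_cv() and cv_objective().
fold_metric <- function(d, train_ids, test_ids, model, spec, params, seed,
                        verbose = FALSE) {
  d_tr <- dataset_subset(d, train_ids)
  d_te <- dataset_subset(d, test_ids)
  task <- d$labels$task
  if (task == "categorical" && length(unique(d_te$labels$values)) < 2)
    return(NA_real_)
  if (model == "multicnn") {
    fit <- fit_multicnn(d_tr, spec = spec, seed = seed, verbose = verbose)
    if (task == "categorical") {
      pr <- predict(fit, d_te, type = "prob")
      if (length(fit$classes) != 2)
        return(mean(predict(fit, d_te, type = "class")$.pred_class ==
                      d_te$labels$values))
      scores <- pr[[paste0(".pred_", fit$classes[2])]]
      roc_auc(d_te$labels$values, scores)
    } else {
      pcc(d_te$labels$values, predict(fit, d_te)$.pred)
    }
  } else {
    fit <- fit_baseline(model, flatten(d_tr), params = params, seed = seed)
    pr <- predict(fit, flatten(d_te))
    if (task == "categorical") {
      scores <- pr[[paste0(".pred_", fit$classes[2])]]
      roc_auc(d_te$labels$values, scores)
    } else {
      pcc(d_te$labels$values, pr$.pred)
    }
  }
}

#' Cross-validated evaluation report
#'
#' Trains the chosen model on each fold complement and scores the held-out
#' fold: AUC for binary categorical tasks (accuracy if more than two classes),
#' Pearson correlation for quantitative tasks. Folds whose held-out part has a
#' single class are skipped with a warning.
#'
#' @param d A `multi_omics_dataset`.
#' @param folds A `fold_plan` from [make_cv_folds()].
#' @param model `"multicnn"` or a baseline kind (`"lr"`, `"svm"`, `"dt"`,
#'   `"rf"`).
#' @param spec Optional [model_spec()] for the CNN.
#' @param params Optional baseline hyperparameters (see [fit_baseline()]).
#' @param seed Integer seed for the per-fold fits.
#' @return A `cv_report`: tibble of per-fold metrics with attributes
#'   `mean`, `sd`, `metric`, `model`.
#' @export
evaluate_cv <- function(d, folds, model = c("multicnn", "lr", "svm", "dt", "rf"),
                        spec = NULL, params = list(), seed = 0) {
  model <- match.arg(model)
  stopifnot(inherits(d, "multi_omics_dataset"), inherits(folds, "fold_plan"))
  ids <- names(folds$assignments)
  per_fold <- numeric(folds$k)
  n_test <- integer(folds$k)
  for (f in seq_len(folds$k)) {
    test_ids <- ids[folds$assignments == f]
    train_ids <- ids[folds$assignments != f]
    n_test[f] <- length(test_ids)
    per_fold[f] <- fold_metric(d, train_ids, test_ids, model, spec, params,
                               seed = seed + f - 1)
    if (is.na(per_fold[f]))
      warning("fold ", f, " held out a single class; skipped", call. = FALSE)
  }
  metric <- if (d$labels$task == "quantitative") "pcc"
  else if (model == "multicnn" || length(unique(d$labels$values)) == 2) "auc"
  else "accuracy"
  ok <- !is.na(per_fold)
  if (!any(ok)) stop("every fold was skipped; cannot evaluate", call. = FALSE)
  out <- tibble::tibble(fold = seq_len(folds$k), metric = per_fold,
                        n_test = n_test)
  structure(out, mean = mean(per_fold[ok]), sd = stats::sd(per_fold[ok]),
            metric = metric, model = model,
            class = c("cv_report", class(out)))
}

#' Summarise a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s, mean %s = %.4f (sd %.4f) over %d folds>\n",
              attr(x, "model"), attr(x, "metric"), attr(x, "mean"),
              attr(x, "sd"), nrow(x)))
  NextMethod()
}

#' Cross-validation objective for hyperparameter search
#'
#' Mean held-out-fold AUC (categorical) or Pearson correlation (quantitative)
#' of a model configuration; the scalar that the tuner maximises. The
#' per-fold values are attached as attribute `"per_fold"`.
#'
#' @param d A `multi_omics_dataset`.
#' @param config Named list of [model_spec()] overrides, optionally with a
#'   `model` entry selecting a baseline instead of the CNN.
#' @param folds A `fold_plan`.
#' @param seed Integer seed.
#' @return A single numeric objective value.
#' @export
cv_objective <- function(d, config, folds, seed = 0) {
  model <- config$model %||% "multicnn"
  config$model <- NULL
  spec <- NULL; params <- list()
  if (model == "multicnn") {
    base <- default_config(d$labels$task,
                           vapply(d$layers, `[[`, "", "omics_type"))
    fields <- intersect(names(config), names(unclass(base)))
    for (f in fields) base[[f]] <- config[[f]]
    if (d$labels$task == "categorical")
      base$n_classes <- length(unique(d$labels$values))
    spec <- base
  } else params <- config
  rep <- evaluate_cv(d, folds, model = model, spec = spec, params = params,
                     seed = seed)
  structure(attr(rep, "mean"), per_fold = rep$metric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
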