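# The four comparison models (L2 logistic regression, RBF SVM, decision tree,
# random forest) fitted on concatenated multi-omics vectors, plus their
# coefficient- or importance-based per-feature scores.

BASELINE_KINDS <- c("lr", "svm", "dt", "rf")

#' Flatten a multi-omics dataset into one feature matrix
#'
#' Concatenates every encoded layer into a samples x total-features matrix
#' with deterministic layer-then-feature-then-channel column order. Column
#' names are layer-qualified (`layer:feature:channel`), giving a bijection
#' between names and columns so channel-level scores can later be
#' re-aggregated per feature.
#'
#' @param d A `multi_omics_dataset`.
#' @return A `flat_dataset`: fields `sample_ids`, `feature_names`, `matrix`,
#'   `labels`, and a `feature_map` tibble (`name, layer, feature, channel`).
#' @export
flatten <- function(d) {
  stopifnot(inherits(d, "multi_omics_dataset"))
  mats <- list(); maps <- list()
  for (nm in names(d$layers)) {
    l <- d$layers[[nm]]
    dd <- dim(l$tensor)
    # feature-major, channel-minor: column (f-1)*C + c
    m <- matrix(aperm(l$tensor, c(1, 3, 2)), dd[1], dd[2] * dd[3])
    map <- tibble::tibble(
      layer = nm,
      feature = rep(l$feature_ids, each = dd[3]),
      channel = rep(l$channels, times = dd[2]))
    map$name <- paste(map$layer, map$feature, map$channel, sep = ":")
    colnames(m) <- map$name
    mats[[nm]] <- m
    maps[[nm]] <- map
  }
  mat <- do.call(cbind, mats)
  map <- dplyr::bind_rows(maps)
  if (anyDuplicated(colnames(mat)))
    stop("flattened feature names are not unique", call. = FALSE)
  structure(list(sample_ids = d$sample_ids, feature_names = colnames(mat),
                 matrix = mat, labels = d$labels,
                 feature_map = map[c("name", "layer", "feature", "channel")]),
            class = "flat_dataset")
}

#' @export
print.flat_dataset <- function(x, ...) {
  cat(sprintf("<flat_dataset: %d samples x %d columns>\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

default_baseline_params <- function(kind) {
  switch(kind,
         lr = list(C = 1.0),
         svm = list(C = 1.0, gamma = "scale"),
         dt = list(max_depth = 30),          # rpart's maximum; effectively unlimited
         rf = list(num_trees = 500))
}

#' Fit a baseline model on a flattened dataset
#'
#' `lr` is logistic (or linear) regression with an L2 penalty (ridge,
#' `lambda = 1 / (n * C)`); `svm` uses the radial-basis-function kernel with
#' probability outputs; `dt` and `rf` are CART and a random forest with
#' impurity importances. Defaults: `C = 1` (lr and svm), `gamma = "scale"`
#' (svm, i.e. `1 / (p * var(x))`), 500 trees (rf), unlimited depth (dt).
#'
#' @param kind One of `"lr"`, `"svm"`, `"dt"`, `"rf"`.
#' @param d A `flat_dataset` from [flatten()].
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed.
#' @return A `trained_baseline`.
#' @export
fit_baseline <- function(kind = BASELINE_KINDS, d, params = list(), seed = 0) {
  kind <- match.arg(kind, BASELINE_KINDS)
  stopifnot(inherits(d, "flat_dataset"))
  p <- utils::modifyList(default_baseline_params(kind), params)
  task <- d$labels$task
  x <- d$matrix
  classes <- NULL
  if (task == "categorical") {
    classes <- sort(unique(d$labels$values))
    if (length(classes) < 2)
      stop("training labels contain a single class", call. = FALSE)
    yf <- factor(d$labels$values, levels = classes)
  } else y <- d$labels$values

  fit <- with_seed(seed, switch(kind,
    lr = {
      lam <- 1 / (nrow(x) * p$C)
      if (task == "categorical")
        glmnet::glmnet(x, yf, family = if (length(classes) == 2) "binomial"
                       else "multinomial",
                       alpha = 0, lambda = lam, standardize = FALSE)
      else glmnet::glmnet(x, y, family = "gaussian", alpha = 0, lambda = lam,
                          standardize = FALSE)
    },
    svm = {
      g <- p$gamma
      if (identical(g, "scale")) {
        v <- stats::var(as.vector(x))
        g <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      }
      # inputs are already encoded/z-scored; internal rescaling would be
      # wrong for one-hot channels and warns on constant columns
      if (task == "categorical")
        e1071::svm(x, yf, kernel = "radial", cost = p$C, gamma = g,
                   probability = TRUE, scale = FALSE)
      else e1071::svm(x, y, kernel = "radial", cost = p$C, gamma = g,
                      scale = FALSE)
    },
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- if (task == "categorical") yf else y
      rpart::rpart(.y ~ ., data = df,
                   method = if (task == "categorical") "class" else "anova",
                   control = rpart::rpart.control(maxdepth = p$max_depth,
                                                  cp = 0.001, xval = 0,
                                                  minsplit = 2,
                                                  minbucket = 1))
    },
    rf = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- if (task == "categorical") yf else y
      # ranger treats seed = 0 as unseeded; shift to keep 0 deterministic
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = p$num_trees,
                     probability = task == "categorical",
                     importance = "impurity",
                     seed = abs(as.integer(seed)) + 1L, num.threads = 1)
    }))
  structure(list(kind = kind, fit = fit, task = task, classes = classes,
                 feature_names = d$feature_names,
                 feature_map = d$feature_map, params = p,
                 seed = as.integer(seed)),
            class = "trained_baseline")
}

#' @export
print.trained_baseline <- function(x, ...) {
  cat(sprintf("<trained_baseline: %s (%s), %d features>\n", x$kind, x$task,
              length(x$feature_names)))
  invisible(x)
}

#' Predict with a trained baseline
#'
#' @param object A `trained_baseline`.
#' @param newdata A `flat_dataset` (or plain matrix with matching columns).
#' @param ... Unused.
#' @return A tibble with `sample_id` and `.pred_<class>` probability columns
#'   (categorical) or `.pred` (quantitative).
#' @export
predict.trained_baseline <- function(object, newdata, ...) {
  if (inherits(newdata, "flat_dataset")) {
    ids <- newdata$sample_ids
    x <- newdata$matrix
  } else {
    x <- as.matrix(newdata)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  if (!identical(colnames(x), object$feature_names))
    stop("feature columns do not match the fitted model", call. = FALSE)
  if (object$task == "quantitative") {
    val <- switch(object$kind,
      lr = as.vector(stats::predict(object$fit, newx = x)),
      svm = as.vector(stats::predict(object$fit, x)),
      dt = as.vector(stats::predict(object$fit,
                                    data.frame(x, check.names = FALSE))),
      rf = stats::predict(object$fit, data.frame(x, check.names = FALSE),
                          num.threads = 1)$predictions)
    return(tibble::tibble(sample_id = ids, .pred = val))
  }
  probs <- switch(object$kind,
    lr = {
      pr <- stats::predict(object$fit, newx = x, type = "response")
      if (length(object$classes) == 2)
        cbind(1 - pr[, 1], pr[, 1])
      else pr[, , 1]
    },
    svm = {
      pr <- attr(stats::predict(object$fit, x, probability = TRUE),
                 "probabilities")
      pr[, object$classes, drop = FALSE]
    },
    dt = stats::predict(object$fit, data.frame(x, check.names = FALSE),
                        type = "prob")[, object$classes, drop = FALSE],
    rf = stats::predict(object$fit, data.frame(x, check.names = FALSE),
                        num.threads = 1)$predictions[, object$classes,
                                                     drop = FALSE])
  probs <- as.matrix(probs)
  colnames(probs) <- paste0(".pred_", object$classes)
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(probs))
}

#' Per-feature importance scores of a baseline model
#'
#' Linear models report absolute coefficients; trees and forests report
#' impurity importances normalised to sum 1. The RBF SVM has no per-feature
#' coefficients, so seeded permutation importance (mean drop in AUC or PCC
#' over `n_shuffles` shuffles of each column, clamped at 0) is used instead;
#' it requires the data the importance should be measured on.
#'
#' @param model A `trained_baseline`.
#' @param d A `flat_dataset`; required for `kind = "svm"`.
#' @param n_shuffles Permutation count for the SVM importance.
#' @param seed Seed for the permutations.
#' @return Named numeric vector of non-negative scores keyed by flat
#'   (layer-qualified) feature names.
#' @export
baseline_importance <- function(model, d = NULL, n_shuffles = 10, seed = 0) {
  stopifnot(inherits(model, "trained_baseline"))
  fn <- model$feature_names
  scores <- switch(model$kind,
    lr = {
      cf <- stats::coef(model$fit)
      if (is.list(cf)) {  # multinomial: max |coef| across classes
        m <- do.call(cbind, lapply(cf, function(ci) abs(as.vector(ci)[-1])))
        stats::setNames(apply(m, 1, max), fn)
      } else stats::setNames(abs(as.vector(cf)[-1]), fn)
    },
    dt = {
      vi <- model$fit$variable.importance
      out <- stats::setNames(rep(0, length(fn)), fn)
      if (length(vi)) {
        out[names(vi)] <- vi
        if (sum(out) > 0) out <- out / sum(out)
      }
      out
    },
    rf = {
      vi <- model$fit$variable.importance
      out <- stats::setNames(rep(0, length(fn)), fn)
      out[names(vi)] <- pmax(vi, 0)
      if (sum(out) > 0) out <- out / sum(out)
      out
    },
    svm = {
      if (is.null(d))
        stop("SVM permutation importance needs the data: pass d = ",
             "flatten(dataset)", call. = FALSE)
      permutation_importance(model, d, n_shuffles, seed)
    })
  scores
}

permutation_importance <- function(model, d, n_shuffles, seed) {
  x <- d$matrix
  score_fun <- function(m) {
    pr <- predict(model, structure(list(sample_ids = d$sample_ids,
                                        matrix = m,
                                        feature_names = colnames(m),
                                        labels = d$labels,
                                        feature_map = d$feature_map),
                                   class = "flat_dataset"))
    if (model$task == "categorical")
      roc_auc(d$labels$values, pr[[paste0(".pred_", model$classes[2])]])
    else pcc(d$labels$values, pr$.pred)
  }
  base <- score_fun(x)
  p <- ncol(x)
  with_seed(seed, {
    drops <- numeric(p)
    for (j in seq_len(p)) {
      acc <- 0
      for (s in seq_len(n_shuffles)) {
        xp <- x
        xp[, j] <- xp[sample.int(nrow(x)), j]
        acc <- acc + (base - score_fun(xp))
      }
      drops[j] <- acc / n_shuffles
    }
    stats::setNames(pmax(drops, 0), colnames(x))
  })
}
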