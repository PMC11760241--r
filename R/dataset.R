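# Sample alignment across layers, train/val/test splitting, CV folds.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards; all of the package's seeded operations use it.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Align encoded layers and labels on their shared samples
#'
#' Inner join on sample ID (exact string match): samples missing from any
#' layer or from the label table are dropped, and the drop is reported. The
#' resulting dataset holds 1-3 encoded layers whose rows are in identical
#' sample order.
#'
#' @param layers A list of 1-3 [encoded_layer()] objects (optionally named;
#'   unnamed layers are named by omics type).
#' @param labels A [label_table()].
#' @return A `multi_omics_dataset`: fields `layers`, `labels`, `sample_ids`.
#' @export
align_samples <- function(layers, labels) {
  if (inherits(layers, "encoded_layer")) layers <- list(layers)
  if (!length(layers) || length(layers) > 3)
    stop("need between 1 and 3 encoded layers, got ", length(layers),
         call. = FALSE)
  stopifnot(all(vapply(layers, inherits, TRUE, "encoded_layer")),
            inherits(labels, "label_table"))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- make.unique(vapply(layers, `[[`, "", "omics_type"))
  common <- labels$sample_ids
  for (l in layers) common <- intersect(common, l$sample_ids)
  if (!length(common))
    stop("no sample ID shared by all layers and the label table", call. = FALSE)
  # keep the label table's order for the shared samples
  common <- labels$sample_ids[labels$sample_ids %in% common]
  total <- unique(c(labels$sample_ids, unlist(lapply(layers, `[[`, "sample_ids"))))
  dropped <- setdiff(total, common)
  if (length(dropped))
    message(sprintf("align_samples: %d sample(s) dropped (absent from some input): %s%s",
                    length(dropped),
                    toString(utils::head(dropped, 5)),
                    if (length(dropped) > 5) ", ..." else ""))
  layers <- lapply(layers, function(l) {
    idx <- match(common, l$sample_ids)
    l$tensor <- l$tensor[idx, , , drop = FALSE]
    l$sample_ids <- common
    l
  })
  lab_idx <- match(common, labels$sample_ids)
  labels$sample_ids <- common
  labels$values <- labels$values[lab_idx]
  structure(list(layers = layers, labels = labels, sample_ids = common),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset: %d samples, %d layer(s) [%s], task %s>\n",
              length(x$sample_ids), length(x$layers),
              toString(names(x$layers)), x$labels$task))
  invisible(x)
}

#' Subset a dataset to a set of sample IDs
#'
#' @param d A `multi_omics_dataset`.
#' @param ids Sample IDs to keep, in the order requested.
#' @return A `multi_omics_dataset` over `ids`.
#' @export
dataset_subset <- function(d, ids) {
  stopifnot(inherits(d, "multi_omics_dataset"))
  ids <- as.character(ids)
  missing <- setdiff(ids, d$sample_ids)
  if (length(missing))
    stop("sample ID(s) not in dataset: ", toString(utils::head(missing, 5)),
         call. = FALSE)
  idx <- match(ids, d$sample_ids)
  d$layers <- lapply(d$layers, function(l) {
    l$tensor <- l$tensor[idx, , , drop = FALSE]
    l$sample_ids <- ids
    l
  })
  d$labels$sample_ids <- ids
  d$labels$values <- d$labels$values[idx]
  d$sample_ids <- ids
  d
}

# Largest-remainder apportionment of n into round(n * fractions) parts.
apportion <- function(n, fractions) {
  ideal <- n * fractions
  base <- floor(ideal)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(ideal - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  base
}

#' Split a dataset into train/validation/test sets
#'
#' Deterministic given `seed`. Categorical tasks are stratified by class;
#' partition sizes follow largest-remainder rounding of `n * fractions`, so
#' 100 samples at (0.6, 0.2, 0.2) give exactly 60/20/20 disjoint sets.
#'
#' @param d A `multi_omics_dataset`.
#' @param fractions Three positive fractions summing to 1 (train, val, test).
#' @param seed Integer seed.
#' @return A `split_plan`: fields `train_ids`, `val_ids`, `test_ids`,
#'   `fractions`, `seed`, `stratified`.
#' @export
split_dataset <- function(d, fractions = c(0.6, 0.2, 0.2), seed = 0) {
  stopifnot(inherits(d, "multi_omics_dataset"))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1", call. = FALSE)
  ids <- d$sample_ids
  n <- length(ids)
  target <- apportion(n, fractions)
  strat <- d$labels$task == "categorical"
  assign_part <- integer(n)  # 1 = train, 2 = val, 3 = test
  with_seed(seed, {
    if (strat) {
      classes <- sort(unique(d$labels$values))
      deficit <- target
      counts <- matrix(0L, length(classes), 3)
      rem <- matrix(0, length(classes), 3)
      for (ci in seq_along(classes)) {
        n_c <- sum(d$labels$values == classes[ci])
        if (n_c < 3)
          stop("class '", classes[ci], "' has fewer samples (", n_c,
               ") than partitions (3)", call. = FALSE)
        ideal <- n_c * fractions
        counts[ci, ] <- floor(ideal)
        rem[ci, ] <- ideal - counts[ci, ]
        deficit <- deficit - counts[ci, ]
      }
      # hand out per-class leftovers against the remaining global deficit
      for (ci in seq_along(classes)) {
        n_c <- sum(d$labels$values == classes[ci])
        left <- n_c - sum(counts[ci, ])
        while (left > 0) {
          open <- which(deficit > 0)
          pick <- open[order(rem[ci, open], decreasing = TRUE)][1]
          counts[ci, pick] <- counts[ci, pick] + 1L
          rem[ci, pick] <- -1
          deficit[pick] <- deficit[pick] - 1L
          left <- left - 1
        }
      }
      for (ci in seq_along(classes)) {
        members <- which(d$labels$values == classes[ci])
        members <- members[sample.int(length(members))]
        assign_part[members] <- rep(1:3, times = counts[ci, ])
      }
    } else {
      perm <- sample.int(n)
      assign_part[perm] <- rep(1:3, times = target)
    }
  })
  structure(list(train_ids = ids[assign_part == 1],
                 val_ids = ids[assign_part == 2],
                 test_ids = ids[assign_part == 3],
                 fractions = fractions, seed = as.integer(seed),
                 stratified = strat),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d/%d/%d train/val/test, seed %d%s>\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed, if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Assign samples to k cross-validation folds
#'
#' Fold sizes differ by at most one; categorical tasks are stratified (class
#' members are dealt round-robin across folds with a running pointer, so both
#' the per-class and the global balance hold). Deterministic given `seed`.
#'
#' @param d A `multi_omics_dataset`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_plan`: fields `k`, `assignments` (named integer vector,
#'   sample ID -> fold in 1..k), `seed`, `stratified`.
#' @export
make_cv_folds <- function(d, k = 5, seed = 0) {
  stopifnot(inherits(d, "multi_omics_dataset"))
  n <- length(d$sample_ids)
  if (!is.numeric(k) || k < 2) stop("k must be an integer >= 2", call. = FALSE)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  fold <- integer(n)
  with_seed(seed, {
    if (d$labels$task == "categorical") {
      pointer <- 0L
      for (cl in sort(unique(d$labels$values))) {
        members <- which(d$labels$values == cl)
        members <- members[sample.int(length(members))]
        fold[members] <- ((pointer + seq_along(members) - 1L) %% k) + 1L
        pointer <- (pointer + length(members)) %% k
      }
    } else {
      perm <- sample.int(n)
      fold[perm] <- ((seq_len(n) - 1L) %% k) + 1L
    }
  })
  assignments <- stats::setNames(fold, d$sample_ids)
  structure(list(k = k, assignments = assignments, seed = as.integer(seed),
                 stratified = d$labels$task == "categorical"),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan: k=%d over %d samples, seed %d%s>\n", x$k,
              length(x$assignments), x$seed,
              if (x$stratified) ", stratified" else ""))
  invisible(x)
}

#' Write or read a split/fold plan as a JSON sidecar
#'
#' @param plan A `split_plan` or `fold_plan`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the plan object (read).
#' @export
write_plan <- function(plan, path) {
  kind <- class(plan)[1]
  obj <- c(list(kind = kind), unclass(plan))
  if (kind == "fold_plan") {
    obj$sample_ids <- names(plan$assignments)
    obj$assignments <- unname(plan$assignments)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  if (identical(kind, "fold_plan")) {
    assignments <- stats::setNames(as.integer(obj$assignments), obj$sample_ids)
    structure(list(k = as.integer(obj$k), assignments = assignments,
                   seed = as.integer(obj$seed),
                   stratified = isTRUE(obj$stratified)), class = "fold_plan")
  } else {
    structure(list(train_ids = as.character(obj$train_ids),
                   val_ids = as.character(obj$val_ids),
                   test_ids = as.character(obj$test_ids),
                   fractions = as.numeric(obj$fractions),
                   seed = as.integer(obj$seed),
                   stratified = isTRUE(obj$stratified)), class = "split_plan")
  }
}
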