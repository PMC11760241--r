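# Biomarker discovery: gradient saliency maps from the CNN, per-feature
# aggregation, dense ranking, top-marker selection, and marker-to-gene mapping.

#' Gradient saliency map of a trained CNN
#'
#' Gradient of a model output with respect to every input entry, per sample,
#' per layer, per channel. For categorical tasks the gradient is taken at the
#' pre-softmax logit of the target class (saturation-safe); the default target
#' is the positive class, i.e. the second of the sorted class levels. Dropout
#' is off and batch normalization uses its running statistics, so the map is
#' deterministic.
#'
#' @param model A `multicnn_model`.
#' @param d A `multi_omics_dataset` matching the model's feature space.
#' @param target Class index (categorical) to differentiate; ignored for
#'   quantitative models.
#' @return A `saliency_gradients` object: named list (one per layer) of
#'   samples x features x channels gradient arrays, with feature IDs and
#'   channel labels attached.
#' @export
saliency_map <- function(model, d, target = NULL) {
  stopifnot(inherits(model, "multicnn_model"),
            inherits(d, "multi_omics_dataset"))
  fw <- mc_model_forward(model, d, training = FALSE)
  n <- nrow(fw$out)
  dout <- matrix(0, n, ncol(fw$out))
  if (model$spec$task == "categorical") {
    if (is.null(target)) target <- min(2L, length(model$classes))
    if (target < 1 || target > length(model$classes))
      stop("target class index out of range", call. = FALSE)
    dout[, target] <- 1
  } else dout[, 1] <- 1
  bw <- mc_backward(model$params, model$spec, model$configs, fw$cache, dout,
                    input_grads = TRUE)
  grads <- bw$dX
  names(grads) <- names(model$layer_meta)
  structure(list(gradients = grads, layer_meta = model$layer_meta,
                 sample_ids = d$sample_ids,
                 target = if (model$spec$task == "categorical") target else NA),
            class = "saliency_gradients")
}

#' @export
print.saliency_gradients <- function(x, ...) {
  cat(sprintf("<saliency_gradients: %d layer(s), %d samples>\n",
              length(x$gradients), length(x$sample_ids)))
  invisible(x)
}

#' Collapse saliency gradients to one score per feature
#'
#' Per feature: the absolute gradient is maximised over encoding channels
#' (so one-hot layers yield one entry per feature, never per channel) and then
#' averaged over samples (`method = "mean"`, default) or maximised over
#' samples (`method = "max"`). Scores are non-negative and invariant to sample
#' order.
#'
#' @param grads A `saliency_gradients` object.
#' @param method Sample aggregation, `"mean"` or `"max"`.
#' @return A tibble: `feature`, `layer`, `saliency`.
#' @export
aggregate_saliency <- function(grads, method = c("mean", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(grads, "saliency_gradients"))
  rows <- lapply(names(grads$gradients), function(nm) {
    g <- abs(grads$gradients[[nm]])
    d <- dim(g)
    # channel max: (n, L, C) -> (n, L)
    per_sample <- g[, , 1, drop = TRUE]
    if (is.null(dim(per_sample))) per_sample <- matrix(per_sample, d[1], d[2])
    if (d[3] > 1)
      for (ch in 2:d[3]) {
        sl <- g[, , ch, drop = TRUE]
        if (is.null(dim(sl))) sl <- matrix(sl, d[1], d[2])
        per_sample <- pmax(per_sample, sl)
      }
    score <- if (method == "mean") colMeans(per_sample)
    else apply(per_sample, 2, max)
    tibble::tibble(feature = grads$layer_meta[[nm]]$feature_ids,
                   layer = nm, saliency = score)
  })
  dplyr::bind_rows(rows)
}

#' Dense rank of saliency scores
#'
#' Rank 1 is the highest saliency; tied values share a rank and ranks have no
#' gaps.
#'
#' @param saliency Numeric vector (optionally named), or a tibble with a
#'   `saliency` column (a `dense_rank` column is then added).
#' @return Integer ranks in the input's order (same container as the input).
#' @export
dense_rank_saliency <- function(saliency) {
  if (is.data.frame(saliency)) {
    saliency$dense_rank <- dense_rank_saliency(saliency$saliency)
    return(saliency)
  }
  if (!length(saliency)) stop("empty saliency vector", call. = FALSE)
  u <- sort(unique(saliency), decreasing = TRUE)
  r <- match(saliency, u)
  names(r) <- names(saliency)
  r
}

#' Build a marker report from a trained CNN
#'
#' Runs [saliency_map()] and [aggregate_saliency()], attaches dense ranks
#' (rank 1 = highest saliency) and orders by decreasing saliency. The report
#' has one row per feature (channels are collapsed) and can be written
#' straight to CSV.
#'
#' @param model A `multicnn_model`.
#' @param d A `multi_omics_dataset`.
#' @param target Optional class index for the saliency target.
#' @param method Sample aggregation passed to [aggregate_saliency()].
#' @return A `marker_report` tibble: `feature, layer, saliency, dense_rank,
#'   gene` (gene is `NA` until [map_markers_to_genes()]), with attributes
#'   `n_samples_used` and `aggregation`.
#' @export
marker_report <- function(model, d, target = NULL, method = "mean") {
  grads <- saliency_map(model, d, target = target)
  rep <- aggregate_saliency(grads, method = method)
  rep <- dense_rank_saliency(rep)
  rep$gene <- NA_character_
  rep <- dplyr::arrange(rep, .data$dense_rank, .data$feature)
  structure(rep, n_samples_used = length(d$sample_ids), aggregation = method,
            class = c("marker_report", class(rep)))
}

#' Marker report from a baseline model's importances
#'
#' Channel-level importance scores are re-aggregated per feature (sum over
#' channels) using the flatten name bijection, then dense-ranked like a
#' saliency report.
#'
#' @param model A `trained_baseline`.
#' @param d The `flat_dataset` it was fitted on (needed for SVM permutation
#'   importance and for the name-to-feature map).
#' @param ... Passed to [baseline_importance()].
#' @return A `marker_report` tibble.
#' @export
baseline_marker_report <- function(model, d, ...) {
  imp <- baseline_importance(model, d, ...)
  map <- model$feature_map
  map$score <- unname(imp[map$name])
  rep <- dplyr::summarise(dplyr::group_by(map, .data$layer, .data$feature),
                          saliency = sum(.data$score), .groups = "drop")
  rep <- rep[c("feature", "layer", "saliency")]
  rep <- dense_rank_saliency(rep)
  rep$gene <- NA_character_
  rep <- dplyr::arrange(rep, .data$dense_rank, .data$feature)
  structure(rep, n_samples_used = length(d$sample_ids),
            aggregation = paste0(model$kind, "_importance"),
            class = c("marker_report", class(rep)))
}

#' Select the top markers of a report
#'
#' Either the top `k` by saliency — ties at the boundary are all included —
#' or every feature with saliency at or above `threshold`. Rows come back
#' sorted by decreasing saliency.
#'
#' @param report A `marker_report`.
#' @param k Number of markers (mutually exclusive with `threshold`).
#' @param threshold Minimum saliency.
#' @return The subset of `report` rows.
#' @export
top_markers <- function(report, k = NULL, threshold = NULL) {
  stopifnot(inherits(report, "marker_report"))
  if (is.null(k) == is.null(threshold))
    stop("give exactly one of k or threshold", call. = FALSE)
  ord <- order(-report$saliency, report$feature)
  rep <- report[ord, ]
  if (!is.null(threshold)) return(rep[rep$saliency >= threshold, ])
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= nrow(rep)) {
    if (k > nrow(rep))
      warning("k (", k, ") exceeds the number of features (", nrow(rep),
              "); returning all", call. = FALSE)
    return(rep)
  }
  cutoff <- rep$saliency[k]
  rep[rep$saliency >= cutoff, ]
}

GENE_TYPED_LAYERS <- c("gene_expression", "protein_expression",
                       "mirna_expression")

#' Map markers to their neighbouring genes
#'
#' Markers found in the annotation are replaced by their linked gene; markers
#' from gene-typed layers (gene/protein/miRNA expression) pass through as
#' themselves when unannotated. Several markers mapping to one gene are
#' deduplicated keeping the best (lowest) dense rank. Everything else is
#' reported unmapped.
#'
#' @param markers A `marker_report` (or subset from [top_markers()]).
#' @param ann A [marker_annotation()].
#' @return List with `genes` (tibble `gene, saliency, dense_rank, feature,
#'   layer`, best rank per gene) and `unmapped` (character vector).
#' @export
map_markers_to_genes <- function(markers, ann = marker_annotation()) {
  stopifnot(inherits(markers, "marker_report"),
            inherits(ann, "marker_annotation"))
  gene <- ann$gene[match(markers$feature, ann$marker)]
  passthrough <- is.na(gene) & markers$layer %in% GENE_TYPED_LAYERS
  gene[passthrough] <- markers$feature[passthrough]
  unmapped <- markers$feature[is.na(gene)]
  mapped <- markers[!is.na(gene), ]
  mapped$gene <- gene[!is.na(gene)]
  genes <- dplyr::slice_min(dplyr::group_by(mapped, .data$gene),
                            order_by = .data$dense_rank, n = 1,
                            with_ties = FALSE)
  genes <- dplyr::arrange(dplyr::ungroup(genes), .data$dense_rank,
                          .data$gene)
  list(genes = genes[c("gene", "saliency", "dense_rank", "feature", "layer")],
       unmapped = unmapped)
}

#' Write a marker report as CSV
#'
#' Columns `feature, layer, saliency, dense_rank, gene`.
#'
#' @param report A `marker_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
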