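# Versioned JSON model archives: architecture spec, fitted parameters at full
# numeric precision, and the preprocessing state (layer names, feature IDs,
# channel orders) needed so inference matches training exactly.

MODEL_FORMAT_VERSION <- 1L

ser_tree <- function(x) {
  if (is.list(x)) lapply(x, ser_tree)
  else list(.dim = if (is.null(dim(x))) length(x) else dim(x),
            .data = as.vector(x))
}

deser_tree <- function(x) {
  if (is.list(x) && !is.null(x$.data)) {
    d <- as.integer(unlist(x$.dim))
    v <- as.numeric(unlist(x$.data))
    if (length(d) > 1) array(v, d) else v
  } else if (is.list(x)) lapply(x, deser_tree)
  else x
}

#' Save a trained model to a JSON archive
#'
#' Everything needed to reproduce predictions is stored: spec, fitted
#' parameters (full precision), batch-norm running statistics, feature ID
#' lists and channel orders per layer, class levels, training history and
#' seed. `load_model(save_model(m))` changes no prediction by more than 1e-6.
#'
#' @param model A `multicnn_model` or `trained_baseline`.
#' @param path Output file path (JSON; baselines use RDS-free JSON only for
#'   the CNN — baseline fits are stored with [saveRDS()] alongside a JSON
#'   descriptor).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "trained_baseline")) {
    saveRDS(model, path)
    return(invisible(path))
  }
  stopifnot(inherits(model, "multicnn_model"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("phenomix")),
    model_class = "multicnn_model",
    spec = unclass(model$spec),
    input_shapes = model$input_shapes,
    configs = model$configs,
    params = ser_tree(model$params),
    state = ser_tree(model$state),
    layer_meta = model$layer_meta,
    layer_names = names(model$layer_meta),
    classes = model$classes,
    history = as.list(model$history),
    best_epoch = model$best_epoch,
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readChar(path, nchars = 1, useBytes = TRUE)
  if (!identical(first, "{")) {
    out <- tryCatch(readRDS(path), error = function(e)
      stop("corrupt or unrecognised model archive: ", path, call. = FALSE))
    if (!inherits(out, "trained_baseline"))
      stop("corrupt or unrecognised model archive: ", path, call. = FALSE)
    return(out)
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt model archive: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$format_version) ||
      obj$format_version != MODEL_FORMAT_VERSION)
    stop("model archive format version ",
         obj$format_version %||% "<missing>", " is not supported (expected ",
         MODEL_FORMAT_VERSION, ")", call. = FALSE)
  spec <- obj$spec
  spec$conv_layers <- lapply(spec$conv_layers, function(cl)
    list(kernel_size = as.integer(cl$kernel_size),
         n_filters = as.integer(cl$n_filters)))
  spec$fc_widths <- as.integer(unlist(spec$fc_widths))
  spec <- do.call(model_spec, spec[c("task", "n_classes", "conv_layers",
                                     "pool_size", "branch_pooling",
                                     "fc_widths", "dropout", "weight_decay",
                                     "leaky_slope",
                                     "learning_rate", "batch_size",
                                     "max_epochs", "patience",
                                     "class_weighting")])
  layer_meta <- lapply(obj$layer_meta, function(lm)
    list(omics_type = lm$omics_type,
         feature_ids = as.character(unlist(lm$feature_ids)),
         channels = as.character(unlist(lm$channels)),
         encoding_kind = lm$encoding_kind))
  names(layer_meta) <- unlist(obj$layer_names)
  hist <- tibble::as_tibble(lapply(obj$history, function(col)
    as.numeric(unlist(lapply(col, function(v) v %||% NA_real_)))))
  structure(list(
    spec = spec,
    input_shapes = lapply(obj$input_shapes, function(s) as.integer(unlist(s))),
    configs = lapply(obj$configs, function(br)
      list(conv = lapply(br$conv, function(cl)
             list(kernel_size = as.integer(cl$kernel_size),
                  n_filters = as.integer(cl$n_filters),
                  pool_size = as.integer(cl$pool_size))),
           out_len = as.integer(br$out_len),
           out_channels = as.integer(br$out_channels),
           rep_width = as.integer(br$rep_width))),
    params = deser_tree(obj$params),
    state = deser_tree(obj$state),
    layer_meta = layer_meta,
    classes = if (!is.null(obj$classes)) as.character(unlist(obj$classes)),
    history = hist,
    best_epoch = as.integer(obj$best_epoch),
    seed = as.integer(obj$seed),
    format_version = MODEL_FORMAT_VERSION), class = "multicnn_model")
}
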