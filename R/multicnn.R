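# The parallel multi-branch convolutional network: one 1-D conv branch per
# omics layer (each conv followed by leaky ReLU and local max pooling), batch
# normalization closing each branch before its representation is flattened
# (or globally max-pooled) and concatenated into a fully connected head with
# dropout and leaky-ReLU activations; softmax cross-entropy (categorical) or
# linear MSE (quantitative); Adam with early stopping on validation loss.

#' Describe a multi-branch CNN architecture
#'
#' @param task `"categorical"` or `"quantitative"`.
#' @param n_classes Number of classes (categorical tasks).
#' @param conv_layers Per-branch convolution stack: a list of
#'   `list(kernel_size, n_filters)` entries applied in order. A kernel larger
#'   than a branch's feature count is clamped to it at build time.
#' @param pool_size Width (= stride) of the non-overlapping max pooling after
#'   each convolution; clamped to the remaining branch length, so tiny inputs
#'   skip pooling. 1 disables pooling.
#' @param branch_pooling How a branch's final activation map becomes its
#'   representation: `"flatten"` (default; keeps position-specific signal) or
#'   `"global_max"` (one value per filter).
#' @param fc_widths Widths of the fully connected layers after concatenation.
#' @param dropout Dropout rate applied to the concatenated representation and
#'   after each fully connected layer.
#' @param weight_decay Decoupled (AdamW-style) L2 decay on the weight
#'   matrices; biases and batch-norm parameters are not decayed.
#' @param leaky_slope Negative slope of the leaky-ReLU activations.
#' @param learning_rate,batch_size,max_epochs,patience Adam learning rate,
#'   minibatch size, epoch cap, and early-stopping patience (epochs without
#'   validation-loss improvement before stopping; best weights are restored).
#' @param class_weighting Weight the loss by inverse class frequency
#'   (categorical tasks with imbalanced cohorts).
#' @return A `model_spec` object.
#' @export
model_spec <- function(task = c("categorical", "quantitative"),
                       n_classes = 2,
                       conv_layers = list(list(kernel_size = 2,
                                               n_filters = 16)),
                       pool_size = 2,
                       branch_pooling = c("flatten", "global_max"),
                       fc_widths = 32,
                       dropout = 0.5,
                       weight_decay = 1e-2,
                       leaky_slope = 0.01,
                       learning_rate = 1e-3,
                       batch_size = 32,
                       max_epochs = 60,
                       patience = 12,
                       class_weighting = TRUE) {
  task <- match.arg(task)
  branch_pooling <- match.arg(branch_pooling)
  stopifnot(dropout >= 0, dropout < 1, all(fc_widths > 0), pool_size >= 1,
            weight_decay >= 0, learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, length(conv_layers) >= 1)
  conv_layers <- lapply(conv_layers, function(cl) {
    cl <- as.list(cl)
    stopifnot(cl$kernel_size >= 1, cl$n_filters >= 1)
    list(kernel_size = as.integer(cl$kernel_size),
         n_filters = as.integer(cl$n_filters))
  })
  if (task == "categorical" && n_classes < 2)
    stop("categorical task needs >= 2 classes", call. = FALSE)
  structure(list(task = task,
                 n_classes = if (task == "categorical") as.integer(n_classes) else 1L,
                 conv_layers = conv_layers,
                 pool_size = as.integer(pool_size),
                 branch_pooling = branch_pooling,
                 fc_widths = as.integer(fc_widths), dropout = dropout,
                 weight_decay = weight_decay,
                 leaky_slope = leaky_slope, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weighting = isTRUE(class_weighting)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  conv <- paste(vapply(x$conv_layers, function(cl)
    sprintf("%dx%d", cl$kernel_size, cl$n_filters), ""), collapse = " -> ")
  cat(sprintf("<model_spec: %s, conv [%s], fc [%s], dropout %.2f>\n",
              x$task, conv, paste(x$fc_widths, collapse = ", "), x$dropout))
  invisible(x)
}

# Per-branch conv configs with kernels and pool widths clamped to the branch
# length; records the branch's final length so the head width is known.
branch_configs <- function(spec, input_shapes) {
  lapply(input_shapes, function(sh) {
    L <- sh[1]
    conv <- lapply(spec$conv_layers, function(cl) {
      k <- min(cl$kernel_size, L)
      L <<- L - k + 1L
      p <- if (spec$pool_size > 1 && L >= spec$pool_size) spec$pool_size else 1L
      L <<- L %/% p
      list(kernel_size = as.integer(k), n_filters = cl$n_filters,
           pool_size = as.integer(p))
    })
    f <- conv[[length(conv)]]$n_filters
    list(conv = conv, out_len = as.integer(L), out_channels = as.integer(f),
         rep_width = as.integer(if (spec$branch_pooling == "global_max") f
                                else L * f))
  })
}

mc_init_params <- function(spec, input_shapes, configs) {
  n_out <- if (spec$task == "categorical") spec$n_classes else 1L
  branches <- vector("list", length(input_shapes))
  concat_width <- 0L
  for (b in seq_along(input_shapes)) {
    C <- input_shapes[[b]][2]
    conv <- list()
    for (j in seq_along(configs[[b]]$conv)) {
      cl <- configs[[b]]$conv[[j]]
      fan_in <- cl$kernel_size * C
      conv[[j]] <- list(W = he_init(fan_in, cl$n_filters, fan_in),
                        b = rep(0, cl$n_filters))
      C <- cl$n_filters
    }
    branches[[b]] <- list(conv = conv,
                          bn = list(gamma = rep(1, C), beta = rep(0, C)))
    concat_width <- concat_width + configs[[b]]$rep_width
  }
  fc <- list()
  w_in <- concat_width
  for (j in seq_along(spec$fc_widths)) {
    fc[[j]] <- list(W = he_init(w_in, spec$fc_widths[j], w_in),
                    b = rep(0, spec$fc_widths[j]))
    w_in <- spec$fc_widths[j]
  }
  # small output-layer init keeps initial logits near zero (stable early loss)
  params <- list(branches = branches, fc = fc,
                 out = list(W = 0.1 * he_init(w_in, n_out, w_in),
                            b = rep(0, n_out)))
  state <- lapply(branches, function(br)
    list(mean = rep(0, length(br$bn$gamma)),
         var = rep(1, length(br$bn$gamma))))
  list(params = params, state = state)
}

#' Build an (untrained) multi-branch CNN graph
#'
#' One convolution branch per input omics layer (1 to 3); each branch's
#' batch-normalized activation map is flattened (or globally max-pooled, per
#' `branch_pooling`) into its representation, and the representations are
#' concatenated before the fully connected head.
#'
#' @param spec A [model_spec()].
#' @param input_shapes List of `c(n_features, n_channels)` pairs, one per
#'   input layer.
#' @param seed Seed for weight initialisation.
#' @return A `multicnn_graph` with initialised parameters.
#' @export
build_model <- function(spec, input_shapes, seed = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (!length(input_shapes) || length(input_shapes) > 3)
    stop("between 1 and 3 input layers required, got ", length(input_shapes),
         call. = FALSE)
  input_shapes <- lapply(input_shapes, function(sh) as.integer(sh[1:2]))
  configs <- branch_configs(spec, input_shapes)
  init <- with_seed(seed, mc_init_params(spec, input_shapes, configs))
  structure(list(spec = spec, input_shapes = input_shapes, configs = configs,
                 params = init$params, state = init$state),
            class = "multicnn_graph")
}

#' @export
print.multicnn_graph <- function(x, ...) {
  cat(sprintf("<multicnn_graph: %d branch(es), task %s>\n",
              length(x$input_shapes), x$spec$task))
  invisible(x)
}

# Full forward pass. Returns output (logits for categorical, values for
# quantitative) plus caches needed for the backward pass.
mc_forward <- function(params, state, spec, configs, Xlist, training = FALSE) {
  slope <- spec$leaky_slope
  b_caches <- vector("list", length(Xlist))
  reps <- vector("list", length(Xlist))
  for (b in seq_along(Xlist)) {
    h <- Xlist[[b]]
    conv_c <- list(); act_c <- list(); pool_c <- list()
    for (j in seq_along(configs[[b]]$conv)) {
      cl <- configs[[b]]$conv[[j]]
      cc <- conv1d_forward(h, params$branches[[b]]$conv[[j]]$W,
                           params$branches[[b]]$conv[[j]]$b, cl$kernel_size)
      ac <- lrelu_forward(cc$Y, slope)
      cc$Y <- NULL
      conv_c[[j]] <- cc
      mp <- mp_forward(ac$y, cl$pool_size)
      h <- mp$Y; mp$Y <- NULL
      ac$y <- NULL
      act_c[[j]] <- ac
      pool_c[[j]] <- mp
    }
    bn_c <- bn_forward(h, params$branches[[b]]$bn$gamma,
                       params$branches[[b]]$bn$beta, state[[b]], training)
    if (training) state[[b]] <- bn_c$state
    if (spec$branch_pooling == "global_max") {
      gp <- gmp_forward(bn_c$Y)
      reps[[b]] <- gp$Y
      tail_c <- list(kind = "global_max", idx = gp$idx, in_dim = gp$in_dim)
    } else {
      dd <- dim(bn_c$Y)
      reps[[b]] <- matrix(bn_c$Y, dd[1], dd[2] * dd[3])
      tail_c <- list(kind = "flatten", in_dim = dd)
    }
    bn_c$Y <- NULL
    b_caches[[b]] <- list(conv = conv_c, act = act_c, pool = pool_c,
                          bn = bn_c, tail = tail_c)
  }
  H <- do.call(cbind, reps)
  widths <- vapply(reps, ncol, 1L)
  rep_drop <- dropout_forward(H, spec$dropout, training)
  H <- rep_drop$Y
  fc_c <- list()
  for (j in seq_along(params$fc)) {
    dn <- dense_forward(H, params$fc[[j]]$W, params$fc[[j]]$b)
    ac <- lrelu_forward(dn$Y, slope)
    dr <- dropout_forward(ac$y, spec$dropout, training)
    fc_c[[j]] <- list(dense = dn, act = list(neg = ac$neg),
                      drop = list(mask = dr$mask))
    H <- dr$Y
  }
  out <- dense_forward(H, params$out$W, params$out$b)
  list(out = out$Y,
       cache = list(branches = b_caches, widths = widths,
                    rep_drop = list(mask = rep_drop$mask), fc = fc_c,
                    out = out),
       state = state)
}

# Backward pass from a gradient on the output. Returns parameter gradients
# and (optionally) gradients w.r.t. the inputs for saliency.
mc_backward <- function(params, spec, configs, cache, dout,
                        input_grads = FALSE) {
  slope <- spec$leaky_slope
  g_out <- dense_backward(dout, cache$out, params$out$W)
  dH <- g_out$dX
  g_fc <- vector("list", length(params$fc))
  for (j in rev(seq_along(params$fc))) {
    dH <- dropout_backward(dH, cache$fc[[j]]$drop)
    dH <- lrelu_backward(dH, cache$fc[[j]]$act, slope)
    g <- dense_backward(dH, cache$fc[[j]]$dense, params$fc[[j]]$W)
    g_fc[[j]] <- list(W = g$dW, b = g$db)
    dH <- g$dX
  }
  dH <- dropout_backward(dH, cache$rep_drop)
  ends <- cumsum(cache$widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  g_branches <- vector("list", length(cache$branches))
  dX_list <- if (input_grads) vector("list", length(cache$branches))
  for (b in seq_along(cache$branches)) {
    bc <- cache$branches[[b]]
    dRep <- dH[, starts[b]:ends[b], drop = FALSE]
    dA <- if (bc$tail$kind == "global_max")
      gmp_backward(dRep, bc$tail)
    else array(dRep, bc$tail$in_dim)
    gbn <- bn_backward(dA, bc$bn, params$branches[[b]]$bn$gamma)
    dA <- gbn$dX
    g_conv <- vector("list", length(bc$conv))
    for (j in rev(seq_along(bc$conv))) {
      dA <- mp_backward(dA, bc$pool[[j]])
      dA <- lrelu_backward(dA, bc$act[[j]], slope)
      g <- conv1d_backward(dA, bc$conv[[j]], params$branches[[b]]$conv[[j]]$W)
      g_conv[[j]] <- list(W = g$dW, b = g$db)
      dA <- g$dX
    }
    if (input_grads) dX_list[[b]] <- dA
    g_branches[[b]] <- list(conv = g_conv,
                            bn = list(gamma = gbn$dgamma, beta = gbn$dbeta))
  }
  list(grads = list(branches = g_branches, fc = g_fc,
                    out = list(W = g_out$dW, b = g_out$db)),
       dX = if (input_grads) dX_list)
}

dataset_tensors <- function(d) lapply(d$layers, `[[`, "tensor")

check_same_features <- function(a, b, what = "dataset") {
  if (!identical(names(a$layers), names(b$layers)))
    stop("layer names differ between train and ", what, ": ",
         toString(names(a$layers)), " vs ", toString(names(b$layers)),
         call. = FALSE)
  for (nm in names(a$layers)) {
    if (!identical(a$layers[[nm]]$feature_ids, b$layers[[nm]]$feature_ids))
      stop("feature IDs of layer '", nm, "' differ between train and ", what,
           call. = FALSE)
    if (!identical(a$layers[[nm]]$channels, b$layers[[nm]]$channels))
      stop("channel order of layer '", nm, "' differs between train and ",
           what, call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a multi-branch CNN
#'
#' Minibatch Adam on cross-entropy (categorical, optionally weighted by
#' inverse class frequency) or mean squared error (quantitative), with early
#' stopping on validation loss; the best-validation weights are restored.
#' Training is reproducible given `seed` (weight initialisation, batch order
#' and dropout all derive from it).
#'
#' @param graph A `multicnn_graph` from [build_model()], defining the
#'   architecture; its weights are re-initialised from `seed`.
#' @param d_train,d_val Training and validation `multi_omics_dataset`s with
#'   identical layer structure. `d_val = NULL` disables early stopping.
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return A `multicnn_model`: spec, fitted parameters, preprocessing state
#'   (layer names, feature IDs, channel orders), class levels, per-epoch
#'   history tibble, and the seed.
#' @export
train_model <- function(graph, d_train, d_val = NULL, seed = 0,
                        verbose = FALSE) {
  stopifnot(inherits(graph, "multicnn_graph"),
            inherits(d_train, "multi_omics_dataset"))
  spec <- graph$spec
  if (!is.null(d_val)) check_same_features(d_train, d_val, "validation")
  Xtr <- dataset_tensors(d_train)
  got <- lapply(Xtr, function(x) as.integer(dim(x)[2:3]))
  for (b in seq_along(got))
    if (!identical(got[[b]], graph$input_shapes[[b]]))
      stop("input shape mismatch on layer ", b, ": graph expects ",
           toString(graph$input_shapes[[b]]), ", data has ",
           toString(got[[b]]), call. = FALSE)
  n <- length(d_train$sample_ids)

  if (spec$task == "categorical") {
    classes <- sort(unique(d_train$labels$values))
    if (length(classes) != spec$n_classes)
      stop("spec declares ", spec$n_classes, " classes but training labels ",
           "have ", length(classes), call. = FALSE)
    y_idx <- match(d_train$labels$values, classes)
    cw <- if (spec$class_weighting) {
      tab <- tabulate(y_idx, length(classes))
      n / (length(classes) * tab)
    } else rep(1, length(classes))
    w <- cw[y_idx]
  } else {
    classes <- NULL
    y_num <- d_train$labels$values
  }
  if (!is.null(d_val)) {
    Xva <- dataset_tensors(d_val)
    yva <- d_val$labels$values
  }

  history <- list()
  out <- with_seed(seed, {
    init <- mc_init_params(spec, graph$input_shapes, graph$configs)
    params <- init$params; state <- init$state
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, state = state, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      perm <- sample.int(n)
      batch_starts <- seq(1, n, by = spec$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        idx <- perm[bs:min(bs + spec$batch_size - 1L, n)]
        Xb <- lapply(Xtr, function(x) x[idx, , , drop = FALSE])
        fw <- mc_forward(params, state, spec, graph$configs, Xb,
                         training = TRUE)
        state <- fw$state
        lg <- if (spec$task == "categorical")
          ce_loss_grad(fw$out, y_idx[idx], w[idx])
        else mse_loss_grad(fw$out, y_num[idx])
        bw <- mc_backward(params, spec, graph$configs, fw$cache, lg$grad)
        stepped <- adam_step(params, bw$grads, opt, spec$learning_rate,
                             spec$weight_decay)
        params <- stepped$params; opt <- stepped$opt
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      train_loss <- ep_loss / n
      if (!is.null(d_val)) {
        fv <- mc_forward(params, state, spec, graph$configs, Xva,
                         training = FALSE)
        if (spec$task == "categorical") {
          yv_idx <- match(yva, classes)
          lv <- ce_loss_grad(fv$out, yv_idx)
          val_loss <- lv$loss
          val_metric <- if (length(classes) == 2 && length(unique(yva)) == 2)
            roc_auc(as.integer(yv_idx == 2), lv$probs[, 2])
          else mean(max.col(lv$probs) == yv_idx)
        } else {
          lv <- mse_loss_grad(fv$out, yva)
          val_loss <- lv$loss
          val_metric <- if (stats::sd(yva) > 0)
            suppressWarnings(stats::cor(as.vector(fv$out), yva)) else NA_real_
        }
      } else {
        val_loss <- NA_real_; val_metric <- NA_real_
      }
      history[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                            val_loss = val_loss, val_metric = val_metric)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  metric %.4f",
                        epoch, train_loss, val_loss, val_metric))
      monitor <- if (is.null(d_val)) train_loss else val_loss
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, params = params, state = state,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
    best
  })

  layer_meta <- lapply(d_train$layers, function(l)
    list(omics_type = l$omics_type, feature_ids = l$feature_ids,
         channels = l$channels, encoding_kind = l$encoding_kind))
  hist_tbl <- tibble::as_tibble(do.call(rbind, history))
  structure(list(spec = spec, input_shapes = graph$input_shapes,
                 configs = graph$configs, params = out$params,
                 state = out$state, layer_meta = layer_meta,
                 classes = classes, history = hist_tbl,
                 best_epoch = out$epoch, seed = as.integer(seed),
                 format_version = 1L),
            class = "multicnn_model")
}

#' Convenience wrapper: encode-ready dataset in, trained CNN out
#'
#' If no validation set is supplied, one stratified fifth of `d_train` is
#' held out for early stopping.
#'
#' @param d_train Training `multi_omics_dataset`.
#' @param d_val Optional validation `multi_omics_dataset`.
#' @param spec A [model_spec()]; defaults to the package default for the
#'   task ([default_config()]).
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return A `multicnn_model`.
#' @export
fit_multicnn <- function(d_train, d_val = NULL, spec = NULL, seed = 0,
                         verbose = FALSE) {
  stopifnot(inherits(d_train, "multi_omics_dataset"))
  if (is.null(spec)) {
    spec <- default_config(d_train$labels$task,
                           vapply(d_train$layers, `[[`, "", "omics_type"))
    if (d_train$labels$task == "categorical")
      spec$n_classes <- length(unique(d_train$labels$values))
  }
  if (is.null(d_val)) {
    folds <- make_cv_folds(d_train, k = 5, seed = seed)
    hold <- names(folds$assignments)[folds$assignments == 1]
    d_val <- dataset_subset(d_train, hold)
    d_train <- dataset_subset(d_train, setdiff(d_train$sample_ids, hold))
  }
  shapes <- lapply(d_train$layers, function(l) dim(l$tensor)[2:3])
  graph <- build_model(spec, shapes, seed = seed)
  train_model(graph, d_train, d_val, seed = seed, verbose = verbose)
}

#' @export
print.multicnn_model <- function(x, ...) {
  cat(sprintf("<multicnn_model: %s, %d branch(es), best epoch %d>\n",
              x$spec$task, length(x$input_shapes), x$best_epoch))
  invisible(x)
}

check_model_features <- function(model, d) {
  if (!setequal(names(d$layers), names(model$layer_meta)))
    stop("layer mismatch: model has [", toString(names(model$layer_meta)),
         "], data has [", toString(names(d$layers)), "]", call. = FALSE)
  for (nm in names(model$layer_meta)) {
    want <- model$layer_meta[[nm]]$feature_ids
    have <- d$layers[[nm]]$feature_ids
    if (!identical(want, have)) {
      missing <- setdiff(want, have); extra <- setdiff(have, want)
      stop("feature mismatch on layer '", nm, "': missing [",
           toString(utils::head(missing, 5)), "], extra [",
           toString(utils::head(extra, 5)), "]", call. = FALSE)
    }
    if (!identical(model$layer_meta[[nm]]$channels, d$layers[[nm]]$channels))
      stop("channel order mismatch on layer '", nm, "'", call. = FALSE)
  }
  invisible(TRUE)
}

mc_model_forward <- function(model, d, training = FALSE) {
  check_model_features(model, d)
  Xlist <- lapply(names(model$layer_meta), function(nm) d$layers[[nm]]$tensor)
  mc_forward(model$params, model$state, model$spec, model$configs, Xlist,
             training = training)
}

#' Predict phenotypes with a trained multi-branch CNN
#'
#' @param object A `multicnn_model`.
#' @param newdata A `multi_omics_dataset` whose layers, feature IDs and
#'   channel orders match the model's preprocessing state.
#' @param type `"prob"` (default for categorical; class probabilities that
#'   sum to 1 per sample), `"class"`, or `"response"` (quantitative value).
#' @param ... Unused.
#' @return A tibble with `sample_id` and prediction columns
#'   (`.pred_<class>` / `.pred_class` / `.pred`), rows in input sample order.
#' @export
predict.multicnn_model <- function(object, newdata,
                                   type = c("prob", "class", "response"),
                                   ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "multi_omics_dataset"))
  fw <- mc_model_forward(object, newdata, training = FALSE)
  if (object$spec$task == "quantitative") {
    return(tibble::tibble(sample_id = newdata$sample_ids,
                          .pred = as.vector(fw$out)))
  }
  probs <- softmax_rows(fw$out)
  colnames(probs) <- paste0(".pred_", object$classes)
  out <- tibble::tibble(sample_id = newdata$sample_ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(probs))
  if (type == "class")
    out <- tibble::tibble(sample_id = newdata$sample_ids,
                          .pred_class = object$classes[max.col(probs)])
  out
}

# Pre-softmax logits (categorical) or raw outputs; used by the saliency map.
predict_logits <- function(model, d) {
  fw <- mc_model_forward(model, d, training = FALSE)
  fw$out
}
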