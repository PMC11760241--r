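# Low-level neural-network primitives for the multi-branch CNN: 1-D valid
# convolution via im2col, leaky ReLU, batch normalization, global max pooling,
# dense layers, dropout, softmax cross-entropy, MSE, and Adam. All tensors are
# base-R arrays (samples, positions, channels); matmuls go through BLAS.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# im2col: (n, L, C) -> (n*Lout, k*C); column for offset j, channel c is
# (c-1)*k + j, matching the row layout of the conv weight matrix W (k*C, F).
im2col <- function(X, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - k + 1L
  P <- matrix(0, n * Lout, k * C)
  for (j in seq_len(k)) {
    sl <- X[, j:(j + Lout - 1L), , drop = FALSE]
    P[, (seq_len(C) - 1L) * k + j] <- matrix(sl, n * Lout, C)
  }
  P
}

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; Lout <- d[2] - k + 1L
  if (Lout < 1)
    stop("kernel size ", k, " exceeds layer length ", d[2], call. = FALSE)
  P <- im2col(X, k)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = array(Y, c(n, Lout, ncol(W))), P = P, in_dim = d, k = k)
}

conv1d_backward <- function(dY, cache, W) {
  d_in <- cache$in_dim; n <- d_in[1]; C <- d_in[3]; k <- cache$k
  Lout <- d_in[2] - k + 1L
  dYm <- matrix(dY, n * Lout, ncol(W))
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  dP <- tcrossprod(dYm, W)
  dX <- array(0, d_in)
  for (j in seq_len(k)) {
    dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), , drop = FALSE] +
      array(dP[, (seq_len(C) - 1L) * k + j], c(n, Lout, C))
  }
  list(dX = dX, dW = dW, db = db)
}

lrelu_forward <- function(x, slope) {
  neg <- x < 0
  list(y = x * (1 - (1 - slope) * neg), neg = neg)
}

lrelu_backward <- function(dy, cache, slope) {
  dy * (1 - (1 - slope) * cache$neg)
}

# Batch norm over a conv activation (n, Lout, F): statistics per filter over
# all samples and positions. `state` carries running mean/var for inference.
bn_forward <- function(X, gamma, beta, state, training) {
  d <- dim(X); m <- d[1] * d[2]; f <- d[3]
  Xm <- matrix(X, m, f)
  if (training) {
    mu <- colMeans(Xm)
    var <- colMeans((Xm - rep(mu, each = m))^2)
    state$mean <- BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * mu
    state$var <- BN_MOMENTUM * state$var + (1 - BN_MOMENTUM) * var
  } else {
    mu <- state$mean
    var <- state$var
  }
  istd <- 1 / sqrt(var + BN_EPS)
  xhat <- (Xm - rep(mu, each = m)) * rep(istd, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(Y = array(y, d), xhat = xhat, istd = istd, state = state,
       training = training, dims = d)
}

bn_backward <- function(dY, cache, gamma) {
  d <- cache$dims; m <- d[1] * d[2]; f <- d[3]
  dy <- matrix(dY, m, f)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(s1 / m, each = m) -
             cache$xhat * rep(s2 / m, each = m)) * rep(cache$istd, each = m)
  } else {
    dx <- dxhat * rep(cache$istd, each = m)
  }
  list(dX = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

gmp_forward <- function(X) {
  d <- dim(X); n <- d[1]; f <- d[3]
  Y <- matrix(0, n, f)
  idx <- matrix(0L, n, f)
  for (ch in seq_len(f)) {
    sl <- X[, , ch, drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, n, d[2])
    w <- max.col(sl, ties.method = "first")
    idx[, ch] <- w
    Y[, ch] <- sl[cbind(seq_len(n), w)]
  }
  list(Y = Y, idx = idx, in_dim = d)
}

gmp_backward <- function(dY, cache) {
  d <- cache$in_dim; n <- d[1]; f <- d[3]
  dX <- array(0, d)
  dX[cbind(rep(seq_len(n), f), as.vector(cache$idx),
           rep(seq_len(f), each = n))] <- as.vector(dY)
  dX
}

dense_forward <- function(X, W, b) {
  Y <- X %*% W
  list(Y = Y + rep(b, each = nrow(Y)), X = X)
}

dense_backward <- function(dY, cache, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted softmax cross-entropy; returns loss and gradient w.r.t. logits.
ce_loss_grad <- function(logits, y_idx, weights = NULL) {
  n <- nrow(logits)
  if (is.null(weights)) weights <- rep(1, n)
  p <- softmax_rows(logits)
  picked <- p[cbind(seq_len(n), y_idx)]
  loss <- sum(weights * -log(pmax(picked, 1e-12))) / sum(weights)
  g <- p
  g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] - 1
  g <- g * (weights / sum(weights))
  list(loss = loss, grad = g, probs = p)
}

mse_loss_grad <- function(pred, y) {
  n <- length(y)
  r <- as.vector(pred) - y
  list(loss = mean(r^2), grad = matrix(2 * r / n, n, 1))
}

# --- parameter-tree utilities (params, grads, Adam moments share a shape) ---

tree_map <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- tree_map(f, a[[i]],
                           if (!is.null(b)) b[[i]], if (!is.null(c)) c[[i]])
    out
  } else f(a, b, c)
}

tree_zeros <- function(a) tree_map(function(x, ...) x * 0, a)

adam_init <- function(params) list(m = tree_zeros(params),
                                   v = tree_zeros(params), t = 0L)

# Adam with decoupled weight decay applied to weight matrices only (biases
# and batch-norm scales are not decayed).
adam_step <- function(params, grads, opt, lr, weight_decay = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                    opt$m, grads)
  opt$v <- tree_map(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                    opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  params <- tree_map(function(p, m, v) {
    upd <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    if (weight_decay > 0 && is.matrix(p)) upd - lr * weight_decay * p else upd
  }, params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# Non-overlapping 1-D max pooling along positions; trailing positions that do
# not fill a window are dropped. s = 1 is the identity.
mp_forward <- function(X, s) {
  if (s <= 1) return(list(Y = X, idx = NULL, s = 1L, in_dim = dim(X)))
  d <- dim(X); Lp <- d[2] %/% s
  base <- (seq_len(Lp) - 1L) * s
  Y <- X[, base + 1L, , drop = FALSE]
  idx <- array(1, dim(Y))
  for (j in seq.int(2L, s)) {
    sl <- X[, base + j, , drop = FALSE]
    upd <- (sl > Y)           # arithmetic update avoids indexed assignment
    Y <- Y + (sl - Y) * upd
    idx <- idx + (j - idx) * upd
  }
  list(Y = Y, idx = idx, s = as.integer(s), in_dim = d)
}

mp_backward <- function(dY, cache) {
  if (cache$s <= 1) return(dY)
  d <- cache$in_dim; Lp <- dim(dY)[2]
  dX <- array(0, d)
  base <- (seq_len(Lp) - 1L) * cache$s
  for (j in seq_len(cache$s))
    dX[, base + j, ] <- dY * (cache$idx == j)
  dX
}
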