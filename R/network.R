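# The 1-D convolutional network.
#
# Architecture (fixed by design, parameterized for width/filters):
#   4 x [ conv(1x5, zero-pad 2, stride 1) -> batch-norm -> ReLU
#         -> max-pool(1x5, stride 5; blocks 1-3 only) ]
#   -> dropout -> fully-connected(-> 2) -> softmax.
# Convolutions preserve width; each pool divides it by 5 (floor), so an
# input of width w reaches the classifier at floor(floor(floor(w/5)/5)/5)
# positions x 128 channels. Implemented with im2col-style matrix products so
# everything runs through BLAS; activations are stored as (width, batch,
# channel) arrays.

#' Architecture hyper-parameters of the fall-detection CNN
#'
#' Defaults are the reference architecture: four convolutional feature
#' extraction blocks with 16/32/64/128 filters of size 1x5, zero padding 2,
#' stride 1, batch normalization and ReLU per block, down-sampling max
#' pooling (size 5, stride 5) after the first three blocks only, and a
#' two-way fully-connected + softmax classifier.
#'
#' @param filters integer vector of per-block filter counts; must be
#'   strictly increasing.
#' @param kernel_width convolution kernel size (samples).
#' @param conv_pad zero-padding per side (samples).
#' @param conv_stride convolution stride.
#' @param pool_width,pool_stride max-pooling window and stride;
#'   `pool_stride = pool_width` gives non-overlapping down-sampling.
#' @param n_pooled_blocks how many leading blocks carry a pooling layer.
#' @param n_classes output classes (2: ADL vs FALL).
#' @return object of class `network_config`.
#' @export
network_config <- function(filters = c(16L, 32L, 64L, 128L),
                           kernel_width = 5L, conv_pad = 2L, conv_stride = 1L,
                           pool_width = 5L, pool_stride = 5L,
                           n_pooled_blocks = 3L, n_classes = 2L) {
  filters <- as.integer(filters)
  if (length(filters) < 1L || any(diff(filters) <= 0L))
    stop_fallcnn("`filters` must be a strictly increasing sequence of filter counts",
                 "fallcnn_config_error")
  if (conv_stride != 1L || kernel_width != 2L * conv_pad + 1L)
    stop_fallcnn("convolutions must preserve width: stride 1 and kernel = 2*pad + 1",
                 "fallcnn_config_error")
  if (pool_width < 1L || pool_stride != pool_width)
    stop_fallcnn("pooling must be non-overlapping down-sampling (stride = width)",
                 "fallcnn_config_error")
  if (n_pooled_blocks < 0L || n_pooled_blocks > length(filters))
    stop_fallcnn("`n_pooled_blocks` must be between 0 and the number of blocks",
                 "fallcnn_config_error")
  if (n_classes != 2L)
    stop_fallcnn("the classifier is binary: `n_classes` must be 2",
                 "fallcnn_config_error")
  structure(list(n_blocks = length(filters), filters = filters,
                 kernel_width = as.integer(kernel_width),
                 conv_pad = as.integer(conv_pad),
                 conv_stride = as.integer(conv_stride),
                 pool_width = as.integer(pool_width),
                 pool_stride = as.integer(pool_stride),
                 n_pooled_blocks = as.integer(n_pooled_blocks),
                 n_classes = as.integer(n_classes)),
            class = "network_config")
}

#' Minimum input width a network configuration admits
#'
#' Every pooled block needs at least `pool_width` positions, so with the
#' default three width-5 pools the input must be at least 5^3 = 125 features
#' wide for one position to survive to the classifier.
#'
#' @param config a [network_config()].
#' @return integer minimum width.
#' @export
network_min_width <- function(config = network_config()) {
  as.integer(config$pool_width^config$n_pooled_blocks)
}

# Closed-form per-block widths after pooling (conv preserves width).
block_widths <- function(input_width, config) {
  w <- as.integer(input_width)
  out <- integer(config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    if (b <= config$n_pooled_blocks) w <- w %/% config$pool_width
    out[b] <- w
  }
  out
}

#' Build an untrained fall-detection CNN
#'
#' Instantiates the layer parameters (He-scaled convolution and
#' fully-connected weights, unit/zero batch-norm scale and shift) for a
#' given input width. The width is the total feature count of the
#' observation windows the model will consume (SMV or TRIAXIAL variant).
#'
#' @param input_width window feature count; must be at least
#'   [network_min_width()].
#' @param config a [network_config()].
#' @param seed integer seed for the weight initialization stream.
#' @return object of class `fallcnn_model` with elements `input_width`,
#'   `config`, `layers`, `classes`, plus training metadata once trained.
#' @examples
#' m <- build_network(1001)
#' network_forward_widths(m)   # 200, 40, 8, 8
#' @export
build_network <- function(input_width, config = network_config(), seed = 1L) {
  input_width <- as.integer(input_width)
  min_w <- network_min_width(config)
  if (input_width < min_w)
    stop_fallcnn(sprintf(
      "input width %d is too narrow for %d pooling blocks: minimum width is %d",
      input_width, config$n_pooled_blocks, min_w), "fallcnn_config_error")
  widths <- block_widths(input_width, config)
  layers <- with_seed(seed, {
    c_in <- 1L
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      c_out <- config$filters[b]
      fan_in <- config$kernel_width * c_in
      lay <- list(type = "block",
                  W = matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)),
                             fan_in, c_out),
                  b = numeric(c_out),
                  gamma = rep(1, c_out), beta = numeric(c_out),
                  running_mean = numeric(c_out), running_var = rep(1, c_out),
                  bn_initialized = FALSE,
                  pooled = b <= config$n_pooled_blocks,
                  c_in = c_in, c_out = c_out)
      c_in <<- c_out
      lay
    })
    # classifier head: zero-initialized (it feeds softmax, not a ReLU), so
    # the untrained network is exactly class-indifferent and early gradient
    # steps point straight along the class-separating direction
    d_fc <- widths[config$n_blocks] * config$filters[config$n_blocks]
    fc <- list(type = "fc",
               W = matrix(0, d_fc, config$n_classes),
               b = numeric(config$n_classes), d_in = d_fc)
    c(blocks, list(fc))
  })
  structure(list(input_width = input_width, config = config, layers = layers,
                 block_widths = widths, classes = c("ADL", "FALL"),
                 seed = as.integer(seed), trained = FALSE,
                 train_config = NULL, history = NULL, best_epoch = NULL),
            class = "fallcnn_model")
}

#' @export
print.fallcnn_model <- function(x, ...) {
  cat(sprintf("<fallcnn_model> input width %d -> blocks [%s] -> fc(2) %s\n",
              x$input_width,
              paste(sprintf("%dx%d", x$block_widths, x$config$filters),
                    collapse = ", "),
              if (x$trained) sprintf("(trained, best epoch %d)", x$best_epoch)
              else "(untrained)"))
  invisible(x)
}

## ---- layer primitives ------------------------------------------------

conv1d_forward <- function(A, W, b, pad) {
  d <- dim(A)                      # (width, batch, c_in)
  w_in <- d[1]; B <- d[2]; c_in <- d[3]
  K <- nrow(W) / c_in
  Ap <- array(0, c(w_in + 2 * pad, B, c_in))
  Ap[(pad + 1):(pad + w_in), , ] <- A
  w_out <- w_in                    # stride 1, kernel = 2*pad + 1
  M <- matrix(0, w_out * B, K * c_in)
  for (cc in seq_len(c_in))
    for (k in seq_len(K))
      M[, (cc - 1L) * K + k] <- Ap[k:(k + w_out - 1), , cc]
  Y <- M %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = array(Y, c(w_out, B, ncol(W))),
       cache = list(M = M, dims = d, K = K, pad = pad))
}

conv1d_backward <- function(dOut, W, cache) {
  d <- cache$dims; w_in <- d[1]; B <- d[2]; c_in <- d[3]
  K <- cache$K; pad <- cache$pad
  w_out <- dim(dOut)[1]
  dY <- matrix(dOut, w_out * B, dim(dOut)[3])
  gW <- crossprod(cache$M, dY)
  gb <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dAp <- array(0, c(w_in + 2 * pad, B, c_in))
  for (cc in seq_len(c_in))
    for (k in seq_len(K)) {
      rng <- k:(k + w_out - 1)
      dAp[rng, , cc] <- dAp[rng, , cc] + matrix(dM[, (cc - 1L) * K + k], w_out, B)
    }
  list(dA = dAp[(pad + 1):(pad + w_in), , , drop = FALSE], gW = gW, gb = gb)
}

bn_forward <- function(A, lay, training, bn_momentum = 0.1, eps = 1e-5) {
  d <- dim(A); n <- d[1] * d[2]; C <- d[3]
  Xm <- A; dim(Xm) <- c(n, C)
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2, mu, "-")
    v <- colMeans(xc^2)
  } else {
    mu <- lay$running_mean
    v <- lay$running_var
    xc <- sweep(Xm, 2, mu, "-")
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
  dim(Y) <- d
  stats <- NULL
  if (training) {
    if (!isTRUE(lay$bn_initialized)) {
      stats <- list(mean = mu, var = v, initialized = TRUE)
    } else {
      stats <- list(mean = (1 - bn_momentum) * lay$running_mean + bn_momentum * mu,
                    var = (1 - bn_momentum) * lay$running_var + bn_momentum * v,
                    initialized = TRUE)
    }
  }
  list(out = Y, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d),
       stats = stats)
}

bn_backward <- function(dOut, lay, cache) {
  d <- cache$dims; n <- d[1] * d[2]; C <- d[3]
  dY <- dOut; dim(dY) <- c(n, C)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  # dX = gamma * inv_sd * (dY - mean(dY) - xhat * mean(dY * xhat))
  dX <- sweep(dY, 2, dbeta / n, "-") -
    sweep(cache$xhat, 2, dgamma / n, "*")
  dX <- sweep(dX, 2, lay$gamma * cache$inv_sd, "*")
  dim(dX) <- d
  list(dA = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(A, size) {
  d <- dim(A); w_in <- d[1]; B <- d[2]; C <- d[3]
  w_out <- w_in %/% size
  A5 <- A[seq_len(size * w_out), , , drop = FALSE]
  m <- matrix(A5, size, w_out * B * C)
  idx <- max.col(t(m), ties.method = "first")
  n <- length(idx)
  vals <- m[idx + (seq_len(n) - 1L) * size]
  list(out = array(vals, c(w_out, B, C)),
       cache = list(idx = idx, dims = d, size = size, w_out = w_out))
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$dims; size <- cache$size; w_out <- cache$w_out
  n <- length(cache$idx)
  dA5 <- numeric(size * n)
  dA5[cache$idx + (seq_len(n) - 1L) * size] <- as.vector(dOut)
  dA <- array(0, d)
  dA[seq_len(size * w_out), , ] <- array(dA5, c(size * w_out, d[2], d[3]))
  dA
}

flatten_forward <- function(A) {
  d <- dim(A)                       # (w, B, C) -> B x (w*C)
  Xf <- aperm(A, c(1, 3, 2))
  dim(Xf) <- c(d[1] * d[3], d[2])
  list(out = t(Xf), dims = d)
}

flatten_backward <- function(dXf, dims) {
  dA <- t(dXf)
  dim(dA) <- c(dims[1], dims[3], dims[2])
  aperm(dA, c(1, 3, 2))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- full forward / backward -----------------------------------------

# x: batch matrix (n x input_width). Returns logits plus caches when
# `keep_cache` (training backward pass needs them). Dropout is applied to
# the flattened features feeding the fully-connected layer, training only.
network_forward <- function(model, x, training = FALSE, dropout_rate = 0,
                            keep_cache = FALSE, bn_momentum = 0.1) {
  stopifnot(is.matrix(x))
  if (ncol(x) != model$input_width)
    stop_fallcnn(sprintf("window width mismatch: model expects %d features, received %d",
                         model$input_width, ncol(x)), "fallcnn_width_error")
  B <- nrow(x)
  A <- array(t(x), c(model$input_width, B, 1L))
  caches <- vector("list", length(model$layers))
  stats <- vector("list", length(model$layers))
  nb <- model$config$n_blocks
  for (i in seq_len(nb)) {
    lay <- model$layers[[i]]
    cv <- conv1d_forward(A, lay$W, lay$b, model$config$conv_pad)
    bn <- bn_forward(cv$out, lay, training, bn_momentum)
    mask <- bn$out > 0
    A <- bn$out * mask
    pc <- NULL
    if (lay$pooled) {
      pl <- maxpool_forward(A, model$config$pool_width)
      A <- pl$out
      pc <- pl$cache
    }
    if (keep_cache)
      caches[[i]] <- list(conv = cv$cache, bn = bn$cache, relu = mask, pool = pc,
                          width = dim(A)[1])
    else
      caches[[i]] <- list(width = dim(A)[1])
    stats[[i]] <- bn$stats
  }
  fl <- flatten_forward(A)
  Xf <- fl$out
  drop_mask <- NULL
  if (training && dropout_rate > 0) {
    drop_mask <- matrix((stats::runif(length(Xf)) >= dropout_rate) /
                          (1 - dropout_rate), nrow(Xf), ncol(Xf))
    Xf <- Xf * drop_mask
  }
  fc <- model$layers[[nb + 1L]]
  logits <- sweep(Xf %*% fc$W, 2, fc$b, "+")
  list(logits = logits,
       caches = if (keep_cache) caches else NULL,
       flat = if (keep_cache) list(Xf = Xf, dims = fl$dims,
                                   drop_mask = drop_mask) else NULL,
       bn_stats = stats,
       widths = vapply(caches[seq_len(nb)], function(cc)
         as.integer(cc$width), integer(1)))
}

# Backward pass from dlogits; returns per-layer gradients.
network_backward <- function(model, fwd, dlogits) {
  nb <- model$config$n_blocks
  fc <- model$layers[[nb + 1L]]
  grads <- vector("list", nb + 1L)
  Xf <- fwd$flat$Xf
  grads[[nb + 1L]] <- list(gW = crossprod(Xf, dlogits), gb = colSums(dlogits))
  dXf <- tcrossprod(dlogits, fc$W)
  if (!is.null(fwd$flat$drop_mask)) dXf <- dXf * fwd$flat$drop_mask
  dA <- flatten_backward(dXf, fwd$flat$dims)
  for (i in rev(seq_len(nb))) {
    lay <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (lay$pooled) dA <- maxpool_backward(dA, cache$pool)
    dA <- dA * cache$relu
    bnb <- bn_backward(dA, lay, cache$bn)
    cvb <- conv1d_backward(bnb$dA, lay$W, cache$conv)
    grads[[i]] <- list(gW = cvb$gW, gb = cvb$gb,
                       dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    dA <- cvb$dA
  }
  grads
}

#' Post-pooling feature-map widths of a model's forward pass
#'
#' Runs an actual forward pass (batch of one) and reports the width of the
#' feature map leaving each block, as measured on the arrays themselves.
#' Useful to verify the width recursion `w -> floor(w / pool_width)` over
#' the pooled blocks.
#'
#' @param model a `fallcnn_model`.
#' @return integer vector, one width per block.
#' @export
network_forward_widths <- function(model) {
  fwd <- network_forward(model, matrix(0, 1, model$input_width))
  as.integer(fwd$widths)
}

#' Classify observation windows
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout) and converts the two softmax probabilities into a label by
#' argmax. An exact 0.5/0.5 tie resolves to FALL: in a fall detector the
#' costlier error is the missed fall.
#'
#' @param object a `fallcnn_model` (typically trained; an untrained model
#'   yields near-chance outputs).
#' @param x numeric matrix of windows (rows) whose width matches
#'   `object$input_width`, or a list as returned by [windows_from_traces()].
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return list with `labels` (factor ADL/FALL) and `probs`
#'   (n x 2 matrix, columns ADL and FALL, rows summing to 1).
#' @export
predict.fallcnn_model <- function(object, x, batch_size = 256L, ...) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x)
  probs <- matrix(NA_real_, n, 2, dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    fwd <- network_forward(object, x[rows, , drop = FALSE])
    probs[rows, ] <- softmax_probs(fwd$logits)
  }
  labels <- factor(ifelse(probs[, "FALL"] >= probs[, "ADL"], "FALL", "ADL"),
                   levels = object$classes)
  list(labels = labels, probs = probs)
}
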