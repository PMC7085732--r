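# Training loop: SGD with momentum, L2 weight decay, dropout, and
# early stopping on validation loss ("validation patience").

#' Training hyper-parameters
#'
#' Defaults are the reference training recipe: stochastic gradient descent with
#' momentum, initial learning rate 1e-4, minibatches of 64 windows, at most
#' 20 epochs, validation once per epoch with patience 3, cross-entropy loss,
#' L2 regularization and dropout as overfitting countermeasures. Momentum
#' 0.9, L2 coefficient 1e-4 and dropout rate 0.5 are the package's explicit
#' defaults where the recipe names only the technique.
#'
#' @param learning_rate positive step size.
#' @param momentum SGD momentum coefficient in `[0, 1)`.
#' @param minibatch_size windows per gradient step (>= 1); a final partial
#'   minibatch is kept rather than discarded.
#' @param max_epochs hard cap on training epochs.
#' @param validation_patience consecutive epoch-evaluations without a new
#'   validation-loss minimum tolerated before stopping (>= 1).
#' @param l2_coefficient L2 penalty on convolution and fully-connected
#'   weights (not biases, not batch-norm parameters).
#' @param dropout_rate drop probability of the single dropout layer placed
#'   immediately before the fully-connected layer (training only).
#' @param bn_momentum EMA momentum of the batch-norm running statistics.
#' @param seed integer seed controlling shuffling and dropout masks.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         minibatch_size = 64L, max_epochs = 20L,
                         validation_patience = 3L, l2_coefficient = 1e-4,
                         dropout_rate = 0.5, bn_momentum = 0.1, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_fallcnn("`learning_rate` must be positive", "fallcnn_config_error")
  if (momentum < 0 || momentum >= 1)
    stop_fallcnn("`momentum` must lie in [0, 1)", "fallcnn_config_error")
  if (minibatch_size < 1L)
    stop_fallcnn("`minibatch_size` must be >= 1", "fallcnn_config_error")
  if (validation_patience < 1L)
    stop_fallcnn("`validation_patience` must be >= 1", "fallcnn_config_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_fallcnn("`dropout_rate` must lie in [0, 1)", "fallcnn_config_error")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 minibatch_size = as.integer(minibatch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_patience = as.integer(validation_patience),
                 l2_coefficient = l2_coefficient,
                 dropout_rate = dropout_rate,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_config")
}

labels_to_onehot <- function(labels, classes) {
  labels <- factor(as.character(labels), levels = classes)
  if (anyNA(labels))
    stop_fallcnn("labels must be ADL or FALL", "fallcnn_config_error")
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

# Cross-entropy loss and accuracy in inference mode (no L2 term).
evaluate_loss <- function(model, x, labels) {
  fwd <- network_forward(model, x)
  p <- softmax_probs(fwd$logits)
  yi <- as.integer(factor(as.character(labels), levels = model$classes))
  loss <- -mean(log(pmax(p[cbind(seq_along(yi), yi)], 1e-12)))
  acc <- mean(max.col(p, ties.method = "last") == yi |
                (p[, 1] == p[, 2] & yi == 2L))
  list(loss = loss, accuracy = acc)
}

new_velocity <- function(layers) {
  lapply(layers, function(lay) {
    v <- list(W = lay$W * 0, b = lay$b * 0)
    if (lay$type == "block") {
      v$gamma <- lay$gamma * 0
      v$beta <- lay$beta * 0
    }
    v
  })
}

sgdm_step <- function(layers, grads, vel, tc) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    gW <- g$gW + tc$l2_coefficient * layers[[i]]$W
    vel[[i]]$W <- tc$momentum * vel[[i]]$W - tc$learning_rate * gW
    layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
    vel[[i]]$b <- tc$momentum * vel[[i]]$b - tc$learning_rate * g$gb
    layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
    if (layers[[i]]$type == "block") {
      vel[[i]]$gamma <- tc$momentum * vel[[i]]$gamma - tc$learning_rate * g$dgamma
      layers[[i]]$gamma <- layers[[i]]$gamma + vel[[i]]$gamma
      vel[[i]]$beta <- tc$momentum * vel[[i]]$beta - tc$learning_rate * g$dbeta
      layers[[i]]$beta <- layers[[i]]$beta + vel[[i]]$beta
    }
  }
  list(layers = layers, vel = vel)
}

# After training, replace the EMA batch-norm running statistics with
# statistics collected over the full training set at the selected weights
# (minibatch-averaged), so inference normalization reflects the final model
# rather than the early training trajectory.
finalize_bn_stats <- function(model, train_x, tc) {
  layers <- model$layers
  n <- nrow(train_x)
  starts <- seq(1L, n, by = tc$minibatch_size)
  nb <- model$config$n_blocks
  acc_mean <- vector("list", nb)
  acc_var <- vector("list", nb)
  for (s in starts) {
    rows <- s:min(s + tc$minibatch_size - 1L, n)
    fwd <- network_forward(model, train_x[rows, , drop = FALSE],
                           training = TRUE, dropout_rate = 0,
                           bn_momentum = 1)
    for (i in seq_len(nb)) {
      acc_mean[[i]] <- rbind(acc_mean[[i]], fwd$bn_stats[[i]]$mean)
      acc_var[[i]] <- rbind(acc_var[[i]], fwd$bn_stats[[i]]$var)
    }
  }
  for (i in seq_len(nb)) {
    layers[[i]]$running_mean <- colMeans(acc_mean[[i]])
    layers[[i]]$running_var <- colMeans(acc_var[[i]])
    layers[[i]]$bn_initialized <- TRUE
  }
  layers
}

#' Train the network with early stopping on validation loss
#'
#' One epoch is a full pass over the shuffled training windows in
#' minibatches. After every epoch the validation cross-entropy is computed
#' in inference mode; training stops at the earlier of `max_epochs` or
#' `validation_patience` consecutive evaluations without a new validation
#' minimum. The returned weights are those of the epoch with minimum
#' validation loss. Identical seeds, data and configuration reproduce the
#' epoch history exactly.
#'
#' @param model an untrained `fallcnn_model` from [build_network()].
#' @param train_x,train_y training windows (matrix, rows = windows) and
#'   labels; both classes must be present.
#' @param val_x,val_y validation windows and labels (non-empty).
#' @param tc a [train_config()].
#' @param verbose emit a JSON log line per epoch.
#' @return the trained `fallcnn_model`, with `history` (a data.frame of
#'   per-epoch train/validation loss and accuracy), `best_epoch`,
#'   `early_stopped`, and `train_config` filled in.
#' @export
train_network <- function(model, train_x, train_y, val_x, val_y,
                          tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "fallcnn_model"), inherits(tc, "train_config"))
  train_x <- as.matrix(train_x); val_x <- as.matrix(val_x)
  if (nrow(train_x) == 0L || nrow(val_x) == 0L)
    stop_fallcnn("training and validation sets must be non-empty",
                 "fallcnn_config_error")
  y_train <- factor(as.character(train_y), levels = model$classes)
  if (nlevels(droplevels(y_train)) < 2L)
    stop_fallcnn("training set contains a single class; cannot train a binary softmax",
                 "fallcnn_config_error")
  Y <- labels_to_onehot(train_y, model$classes)
  n <- nrow(train_x)

  with_seed(tc$seed, {
    layers <- model$layers
    vel <- new_velocity(layers)
    best_loss <- Inf; best_epoch <- 0L; best_layers <- layers
    strikes <- 0L; early <- FALSE
    hist <- vector("list", tc$max_epochs)

    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tc$minibatch_size)
      for (s in starts) {
        rows <- ord[s:min(s + tc$minibatch_size - 1L, n)]
        model$layers <- layers
        fwd <- network_forward(model, train_x[rows, , drop = FALSE],
                               training = TRUE,
                               dropout_rate = tc$dropout_rate,
                               keep_cache = TRUE, bn_momentum = tc$bn_momentum)
        # fold the fresh batch statistics into the running estimates
        for (i in seq_len(model$config$n_blocks)) {
          st <- fwd$bn_stats[[i]]
          layers[[i]]$running_mean <- st$mean
          layers[[i]]$running_var <- st$var
          layers[[i]]$bn_initialized <- TRUE
        }
        p <- softmax_probs(fwd$logits)
        dlogits <- (p - Y[rows, , drop = FALSE]) / length(rows)
        model$layers <- layers
        grads <- network_backward(model, fwd, dlogits)
        upd <- sgdm_step(layers, grads, vel, tc)
        layers <- upd$layers; vel <- upd$vel
      }
      model$layers <- layers
      tr <- evaluate_loss(model, train_x, train_y)
      va <- evaluate_loss(model, val_x, val_y)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = tr$loss, train_acc = tr$accuracy,
                                  val_loss = va$loss, val_acc = va$accuracy)
      log_json(verbose, "epoch", epoch = epoch, train_loss = tr$loss,
               train_acc = tr$accuracy, val_loss = va$loss, val_acc = va$accuracy)
      if (va$loss < best_loss) {
        best_loss <- va$loss; best_epoch <- epoch
        best_layers <- layers; strikes <- 0L
      } else {
        strikes <- strikes + 1L
        if (strikes >= tc$validation_patience) { early <- TRUE; break }
      }
    }

    model$layers <- best_layers
    model$layers <- finalize_bn_stats(model, train_x, tc)
    model$trained <- TRUE
    model$train_config <- tc
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    model$best_epoch <- best_epoch
    model$early_stopped <- early
    model
  })
}
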