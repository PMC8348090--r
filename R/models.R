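#' Classifier architecture specification
#'
#' @param arch `"conv1d"`, `"conv2d"`, or `"lstm"`.
#' @param input_shape `(t_fixed, n_mels)` of the spectrogram input
#'   (default `c(98, 26)`).
#' @param n_classes Number of behavior classes (fixed at 3).
#' @param dropout Dropout rate applied before the penultimate dense layer
#'   (default 0.1).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(arch = c("lstm", "conv1d", "conv2d"),
                            input_shape = c(98L, 26L), n_classes = 3L,
                            dropout = 0.1, seed = 1L) {
  arch <- match.arg(arch)
  if (n_classes != 3L) stop("n_classes is fixed at 3", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("need 0 <= dropout < 1", call. = FALSE)
  structure(list(arch = arch, input_shape = as.integer(input_shape),
                 n_classes = 3L, dropout = dropout,
                 activations = c(feedforward = "relu", recurrent = "tanh"),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Training configuration
#'
#' Thirty epochs of Adam on categorical cross-entropy, the protocol used
#' for all three architectures; optimizer, learning rate, and batch size
#' are conventional small-audio-classifier defaults.
#'
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", learning_rate = learning_rate,
                 loss = "categorical_cross_entropy", seed = as.integer(seed)),
            class = "train_config")
}

# pooled output length along one axis after `k`-kernel valid conv + pool-2
conv_pool_len <- function(len, kernel = 3L) (len - kernel + 1L) %/% 2L

new_network <- function(spec, layers, input_dims) {
  n_params <- sum(vapply(layers, function(l) {
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), 0))
  }, 0))
  structure(list(spec = spec, layers = layers, input_dims = input_dims,
                 parameter_count = as.integer(n_params)),
            class = "jaw_network")
}

#' Build the time-distributed Conv1D classifier
#'
#' Each spectrogram frame's 26 Mel energies pass through two shared 1-D
#' convolution + max-pool stages (32 then 64 filters, kernel 3), the
#' per-frame features are flattened across time, and two dense layers
#' with a softmax head produce the 3-class distribution.
#'
#' @param spec A [classifier_spec].
#' @return An untrained `jaw_network`.
#' @export
build_conv1d <- function(spec = classifier_spec("conv1d")) {
  t_fixed <- spec$input_shape[1]; n_mels <- spec$input_shape[2]
  p1 <- conv_pool_len(n_mels)        # 26 -> 12
  p2 <- conv_pool_len(p1)            # 12 -> 5
  if (p2 < 1L) stop("input too narrow for two conv/pool stages", call. = FALSE)
  with_seed(spec$seed, {
    layers <- list(
      nn_td_conv1d(1L, 32L),
      nn_pool_freq(),
      nn_td_conv1d(32L, 64L),
      nn_pool_freq(),
      nn_flatten(),
      nn_dropout(spec$dropout),
      nn_dense(t_fixed * p2 * 64L, 11L, "relu"),
      nn_dense(11L, 3L, "linear")
    )
  })
  new_network(spec, layers, c(t_fixed, n_mels, 1L))
}

#' Build the Conv2D classifier
#'
#' Treats the whole spectrogram as an image: two 3x3 convolution +
#' 2x2 max-pool stages (16 then 32 filters), flatten, dense, softmax.
#'
#' @param spec A [classifier_spec].
#' @return An untrained `jaw_network`.
#' @export
build_conv2d <- function(spec = classifier_spec("conv2d")) {
  t_fixed <- spec$input_shape[1]; n_mels <- spec$input_shape[2]
  h2 <- conv_pool_len(conv_pool_len(t_fixed))
  w2 <- conv_pool_len(conv_pool_len(n_mels))
  if (h2 < 1L || w2 < 1L) stop("input too small for two conv/pool stages", call. = FALSE)
  with_seed(spec$seed, {
    layers <- list(
      nn_conv2d(1L, 16L),
      nn_pool2d(),
      nn_conv2d(16L, 32L),
      nn_pool2d(),
      nn_flatten(),
      nn_dropout(spec$dropout),
      nn_dense(h2 * w2 * 32L, 116L, "relu"),
      nn_dense(116L, 3L, "linear")
    )
  })
  new_network(spec, layers, c(t_fixed, n_mels, 1L))
}

#' Build the bidirectional LSTM classifier
#'
#' Two serial recurrent units; in each, a shared per-frame dense layer
#' (the skip path) runs alongside a bidirectional LSTM whose forward and
#' backward hidden states read the spectrogram in both time directions,
#' and the two feature streams are concatenated. Dense layers and a
#' softmax head follow.
#'
#' @param spec A [classifier_spec].
#' @return An untrained `jaw_network`.
#' @export
build_lstm <- function(spec = classifier_spec("lstm")) {
  t_fixed <- spec$input_shape[1]; n_mels <- spec$input_shape[2]
  with_seed(spec$seed, {
    layers <- list(
      nn_lstm_unit(n_mels, 32L, 32L),
      nn_lstm_unit(96L, 32L, 32L),
      nn_flatten(),
      nn_dropout(spec$dropout),
      nn_dense(t_fixed * 96L, 36L, "relu"),
      nn_dense(36L, 3L, "linear")
    )
  })
  new_network(spec, layers, c(t_fixed, n_mels))
}

build_network <- function(spec) {
  switch(spec$arch,
         conv1d = build_conv1d(spec),
         conv2d = build_conv2d(spec),
         lstm = build_lstm(spec))
}

#' @export
print.jaw_network <- function(x, ...) {
  cat(sprintf("<jaw_network> %s, input (%s), %d parameters%s\n",
              x$spec$arch, paste(x$spec$input_shape, collapse = " x "),
              x$parameter_count,
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

labels_to_onehot <- function(labels) {
  f <- factor(labels, levels = BEHAVIORS)
  if (anyNA(f)) stop("labels must be in {bite, chew, chew_bite}", call. = FALSE)
  y <- matrix(0, length(f), 3L)
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

# stack a list of t_fixed x n_mels matrices into (n, dims...) with an
# explicit trailing channel axis when the network expects one
stack_inputs <- function(x, input_dims) {
  if (is.list(x)) {
    x <- vapply(x, function(m) {
      if (inherits(m, "mel_spectrogram")) m <- m$values
      if (!identical(dim(m), as.integer(input_dims[1:2]))) {
        stop(sprintf(
          "input shape (%s) does not match network input (%d, %d)",
          paste(dim(m), collapse = ", "), input_dims[1], input_dims[2]),
          call. = FALSE)
      }
      as.numeric(m)
    }, numeric(prod(input_dims[1:2])))
    x <- t(x)
    dim(x) <- c(nrow(x), input_dims[1], input_dims[2])
  }
  d <- dim(x)
  if (length(d) == 2L) {  # single example
    x <- array(x, c(1L, d))
    d <- dim(x)
  }
  if (!all(d[2:3] == input_dims[1:2])) {
    stop(sprintf("input shape (%d, %d) does not match network input (%d, %d)",
                 d[2], d[3], input_dims[1], input_dims[2]), call. = FALSE)
  }
  if (length(input_dims) == 3L) dim(x) <- c(d[1], input_dims)
  x
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    ps <- layer_param_names(l)
    if (!length(ps)) return(NULL)
    stats <- lapply(ps, function(p) {
      list(m = array(0, dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim(l[[p]]) %||% length(l[[p]])))
    })
    names(stats) <- ps
    stats
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      state[[i]][[p]] <- st
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    }
  }
  list(layers = layers, state = state)
}

eval_network <- function(network, x, y_onehot, batch_size = 128L) {
  n <- dim(x)[1]
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- index_batch(x, idx)
    probs <- softmax_rows(network_forward(network$layers, xb, FALSE)$out)
    yb <- y_onehot[idx, , drop = FALSE]
    loss <- loss - sum(log(pmax(probs[yb == 1], 1e-12)))
    correct <- correct + sum(max.col(probs) == max.col(yb))
  }
  c(loss = loss / n, acc = correct / n)
}

index_batch <- function(x, idx) {
  d <- dim(x)
  if (length(d) == 3L) x[idx, , , drop = FALSE] else x[idx, , , , drop = FALSE]
}

#' Train a classifier network
#'
#' Runs the full training protocol: feature standardization fitted on the
#' training set, minibatch Adam on categorical cross-entropy for exactly
#' `config$epochs` epochs, with per-epoch training and validation loss
#' and accuracy recorded. Fully deterministic given the build and
#' training seeds.
#'
#' @param network An untrained `jaw_network` from one of the builders.
#' @param x_train Training inputs: a list of `t_fixed x n_mels` matrices
#'   (or [log_mel_spectrogram()] outputs) or an `(n, t_fixed, n_mels)`
#'   array.
#' @param y_train Behavior labels for the training inputs.
#' @param x_val,y_val Optional validation set in the same formats.
#' @param config A [train_config].
#' @return The trained network, of class `c("jaw_classifier",
#'   "jaw_network")`, with a `history` data.frame of `config$epochs` rows.
#' @export
train_classifier <- function(network, x_train, y_train,
                             x_val = NULL, y_val = NULL,
                             config = train_config()) {
  stopifnot(inherits(network, "jaw_network"), inherits(config, "train_config"))
  if (length(y_train) == 0L) stop("empty training set", call. = FALSE)
  x <- stack_inputs(x_train, network$input_dims)
  y <- labels_to_onehot(y_train)
  n <- dim(x)[1]
  if (n != nrow(y)) stop("x_train/y_train length mismatch", call. = FALSE)

  mu <- mean(x); sdev <- stats::sd(as.vector(x))
  if (!is.finite(sdev) || sdev == 0) sdev <- 1
  x <- (x - mu) / sdev
  has_val <- !is.null(x_val)
  if (has_val) {
    xv <- (stack_inputs(x_val, network$input_dims) - mu) / sdev
    yv <- labels_to_onehot(y_val)
  }

  layers <- network$layers
  state <- adam_init(layers)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_, val_loss = NA_real_,
                        val_accuracy = NA_real_)
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        xb <- index_batch(x, idx)
        yb <- y[idx, , drop = FALSE]
        fwd <- network_forward(layers, xb, training = TRUE)
        probs <- softmax_rows(fwd$out)
        batch_loss <- -sum(log(pmax(probs[yb == 1], 1e-12)))
        if (!is.finite(batch_loss)) {
          stop(sprintf(
            "non-finite loss at epoch %d (step %d); try a lower learning rate",
            epoch, step + 1L), call. = FALSE)
        }
        ep_loss <- ep_loss + batch_loss
        ep_correct <- ep_correct + sum(max.col(probs) == max.col(yb))
        dlogits <- (probs - yb) / length(idx)
        grads <- network_backward(layers, fwd$caches, dlogits)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, config$learning_rate, step)
        layers <- upd$layers
        state <- upd$state
      }
      history$loss[epoch] <- ep_loss / n
      history$accuracy[epoch] <- ep_correct / n
      if (has_val) {
        vm <- eval_network(list(layers = layers), xv, yv)
        history$val_loss[epoch] <- vm["loss"]
        history$val_accuracy[epoch] <- vm["acc"]
      }
    }
  })
  network$layers <- layers
  network$history <- history
  network$scaling <- c(mean = mu, sd = sdev)
  network$train_config <- config
  class(network) <- c("jaw_classifier", "jaw_network")
  network
}

#' Fit an ingestive-behavior sound classifier
#'
#' One-call interface: builds the requested architecture and trains it on
#' fixed-shape log-Mel spectrograms.
#'
#' @param x Training inputs (list of matrices/spectrograms or an array).
#' @param y Behavior labels (`"bite"`, `"chew"`, `"chew_bite"`).
#' @param arch Architecture: `"lstm"` (default), `"conv1d"`, `"conv2d"`.
#' @param x_val,y_val Optional validation data.
#' @param epochs,dropout,batch_size,learning_rate Training
#'   hyperparameters; see [train_config()].
#' @param input_shape Spectrogram shape `(t_fixed, n_mels)`.
#' @param seed Seed covering both initialization and training.
#' @return A fitted `jaw_classifier`.
#' @examples
#' \donttest{
#' specs <- default_sound_specs()
#' segs <- lapply(seq_along(specs) * 7L, function(s)
#'   generate_segment(specs[[(s / 7 - 1) %% 12 + 1]], s))
#' feats <- lapply(segs, function(s) to_fixed_input(log_mel_spectrogram(s)))
#' labels <- vapply(segs, function(s) s$behavior, "")
#' fit <- jaw_classifier(feats, labels, arch = "conv1d", epochs = 2)
#' predict(fit, feats[1:3])
#' }
#' @export
jaw_classifier <- function(x, y, arch = c("lstm", "conv1d", "conv2d"),
                           x_val = NULL, y_val = NULL, epochs = 30L,
                           dropout = 0.1, batch_size = 32L,
                           learning_rate = 1e-3,
                           input_shape = c(98L, 26L), seed = 1L) {
  arch <- match.arg(arch)
  spec <- classifier_spec(arch, input_shape = input_shape,
                          dropout = dropout, seed = seed)
  net <- build_network(spec)
  train_classifier(net, x, y, x_val, y_val,
                   train_config(epochs, batch_size, learning_rate, seed))
}

#' Predict behaviors for new spectrograms
#'
#' @param object A fitted `jaw_classifier`.
#' @param x Inputs in the formats accepted by [train_classifier()].
#' @param type `"class"` (default) for labels or `"prob"` for the 3-class
#'   probability matrix.
#' @param ... Unused.
#' @return A character vector of labels or an `n x 3` probability matrix
#'   (columns bite, chew, chew_bite), in input order.
#' @export
predict.jaw_classifier <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xx <- stack_inputs(x, object$input_dims)
  xx <- (xx - object$scaling["mean"]) / object$scaling["sd"]
  n <- dim(xx)[1]
  probs <- matrix(0, n, 3L, dimnames = list(NULL, BEHAVIORS))
  for (start in seq(1L, n, by = 128L)) {
    idx <- start:min(start + 127L, n)
    probs[idx, ] <- softmax_rows(
      network_forward(object$layers, index_batch(xx, idx), FALSE)$out)
  }
  if (type == "prob") probs else BEHAVIORS[max.col(probs)]
}

#' @export
print.jaw_classifier <- function(x, ...) {
  h <- x$history
  cat(sprintf("<jaw_classifier> %s, %d parameters, trained %d epochs\n",
              x$spec$arch, x$parameter_count, nrow(h)))
  cat(sprintf("final training loss %.4f, accuracy %.3f\n",
              h$loss[nrow(h)], h$accuracy[nrow(h)]))
  if (!is.na(h$val_accuracy[nrow(h)])) {
    cat(sprintf("final validation loss %.4f, accuracy %.3f\n",
                h$val_loss[nrow(h)], h$val_accuracy[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.jaw_classifier <- function(object, ...) {
  print(object)
  cat("\nlayers:\n")
  for (l in object$layers) {
    np <- sum(vapply(layer_param_names(l), function(p) length(l[[p]]), 0))
    cat(sprintf("  %-10s %d parameters\n", l$type, np))
  }
  invisible(object)
}

#' Plot training and validation curves
#'
#' @param x A fitted `jaw_classifier`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.jaw_classifier <- function(x, ...) {
  h <- x$history
  cols <- c("accuracy", "val_accuracy")
  cols <- cols[colSums(!is.na(h[cols])) > 0]
  graphics::matplot(h$epoch, h[cols], type = "l", lty = 1:2, col = c(1, 2),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", legend = cols, lty = 1:2, col = c(1, 2),
                   bty = "n")
  invisible(x)
}
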