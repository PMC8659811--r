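#' @title Text CNN with multi-scale kernels and 1-max pooling
#' @description The binary staging classifier: convolution kernels of several
#'   window lengths slide over the document matrix; each feature map is
#'   reduced by 1-max pooling; the pooled feature vector (length = number of
#'   kernels) passes through dropout and a fully connected 2-way softmax.
#'   Trained by minibatch stochastic gradient descent with backpropagation.
#' @name cnn_classifier
NULL

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x) as.numeric(x > 0)),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2),
    identity = list(f = identity, df = function(x) rep(1, length(x))),
    stop("unknown activation: ", name)
  )
}

#' Construct a convolution kernel
#'
#' @param weights An `m x n` numeric matrix (window length x embedding dim).
#' @param bias Scalar bias.
#' @return A list of class `conv_kernel`.
#' @export
conv_kernel <- function(weights, bias = 0) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) >= 1, is.numeric(weights), length(bias) == 1L)
  structure(list(W = weights, b = as.numeric(bias), m = nrow(weights)),
            class = "conv_kernel")
}

#' Construct an (untrained) text-CNN staging classifier
#'
#' Defaults follow the reference configuration: three kernel window sizes
#' 3/4/5 (one kernel each), 1-max pooling, a fully connected layer with
#' dropout 0.5 and softmax output, and SGD training.
#'
#' @param n Embedding dimension of the document matrices.
#' @param windows Integer kernel window lengths.
#' @param kernels_per_window Kernels per window length (capacity knob).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param dropout_rate Dropout probability on the pooled feature vector
#'   during training, in `[0, 1)`.
#' @param lr SGD learning rate (constant).
#' @param batch_size Minibatch size.
#' @param epochs Default epoch budget used by [cnn_train()] when not
#'   overridden.
#' @param seed Seed for weight initialisation.
#' @return A list of class `cnn_model`.
#' @export
cnn_model <- function(n, windows = c(3L, 4L, 5L), kernels_per_window = 1L,
                      activation = "relu", dropout_rate = 0.5,
                      lr = 0.05, batch_size = 32L, epochs = 256L, seed = 1L) {
  stopifnot(n >= 1, all(windows >= 1), kernels_per_window >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  activation_fun(activation)  # validate name
  with_seed(derive_seed(seed, "cnn-init"), {
    kernels <- list()
    for (m in rep(as.integer(windows), each = kernels_per_window)) {
      sd0 <- sqrt(2 / (m * n))
      kernels[[length(kernels) + 1L]] <-
        conv_kernel(matrix(stats::rnorm(m * n, 0, sd0), m, n), bias = 0)
    }
    K <- length(kernels)
    structure(list(
      n = as.integer(n), kernels = kernels, activation = activation,
      fc_W = matrix(stats::rnorm(2 * K, 0, sqrt(1 / K)), 2, K),
      fc_b = numeric(2),
      dropout_rate = dropout_rate,
      config = list(optimizer = "sgd", lr = lr,
                    batch_size = as.integer(batch_size),
                    epochs = as.integer(epochs), seed = as.integer(seed)),
      history = numeric(0)
    ), class = "cnn_model")
  })
}

#' Convolution feature map of one kernel over a document matrix
#'
#' Entry `i` is `f(<K, X[i:(i+m-1), ]> + b)` where `<.,.>` is the
#' elementwise-product sum over the window.
#'
#' @param matrix A `document_matrix` (or plain numeric matrix) with at least
#'   `m` rows.
#' @param kernel A [conv_kernel()].
#' @param activation Activation name (default `"relu"`).
#' @return Numeric vector of length `nrow(matrix) - m + 1`.
#' @export
#' @examples
#' X <- matrix(1:4, 4, 1)
#' conv_feature(X, conv_kernel(matrix(1, 2, 1)), "identity")  # 3 5 7
conv_feature <- function(matrix, kernel, activation = "relu") {
  stopifnot(inherits(kernel, "conv_kernel"))
  X <- unclass(matrix)
  num <- nrow(X); m <- kernel$m
  if (num < m) stop("document too short for window: num=", num, " < m=", m)
  pre <- conv_preact(X, kernel)
  activation_fun(activation)$f(pre)
}

# Pre-activation feature map (no nonlinearity); vectorised over positions.
conv_preact <- function(X, kernel) {
  num <- nrow(X); m <- kernel$m
  L <- num - m + 1L
  if (L < 1L) stop("document too short for window: num=", num, " < m=", m)
  A <- X %*% t(kernel$W)            # num x m; col r = <X[i,], W[r,]>
  out <- numeric(L)
  for (r in seq_len(m)) out <- out + A[r:(r + L - 1L), r]
  out + kernel$b
}

#' 1-max pooling
#'
#' @param feature Non-empty numeric vector (a convolution feature map).
#' @return The maximum element.
#' @export
max_pool <- function(feature) {
  if (!length(feature)) stop("cannot pool an empty feature map")
  max(feature)
}

# Full forward pass with cache for backprop.
# dropout_mask: NULL (evaluation) or a 0/scale vector of length K.
cnn_forward_cache <- function(X, model, dropout_mask = NULL) {
  act <- activation_fun(model$activation)
  K <- length(model$kernels)
  z <- numeric(K); argmax <- integer(K); pre_at_max <- numeric(K)
  for (k in seq_len(K)) {
    pre <- conv_preact(X, model$kernels[[k]])
    fm <- act$f(pre)
    i_star <- which.max(fm)
    z[k] <- fm[i_star]
    argmax[k] <- i_star
    pre_at_max[k] <- pre[i_star]
  }
  z_drop <- if (is.null(dropout_mask)) z else z * dropout_mask
  scores <- as.numeric(model$fc_W %*% z_drop + model$fc_b)
  probs <- softmax_vec(scores)
  list(z = z, z_drop = z_drop, argmax = argmax, pre_at_max = pre_at_max,
       probs = probs, mask = dropout_mask)
}

#' Forward pass: positive-class probability of a document
#'
#' In evaluation mode (`training = FALSE`, the default) dropout is disabled
#' and the output is deterministic. In training mode a dropout mask drawn
#' from the current RNG stream is applied to the pooled feature vector.
#'
#' @param matrix A document matrix with at least `max(window)` rows.
#' @param model A `cnn_model`.
#' @param training Logical; apply dropout?
#' @return The probability `eta` in `[0, 1]` that the document is a positive
#'   sample of the model's label.
#' @export
cnn_forward <- function(matrix, model, training = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  X <- unclass(matrix)
  if (ncol(X) != model$n) {
    stop("document matrix has ", ncol(X), " columns; model expects ", model$n)
  }
  mask <- NULL
  if (training && model$dropout_rate > 0) {
    keep <- stats::runif(length(model$kernels)) >= model$dropout_rate
    mask <- keep / (1 - model$dropout_rate)
  }
  cache <- cnn_forward_cache(X, model, mask)
  cache$probs[2]
}

#' Positive-class probabilities for a list of documents (evaluation mode)
#'
#' @param model A `cnn_model`.
#' @param xs List of document matrices.
#' @return Numeric vector of `eta` values.
#' @export
cnn_predict <- function(model, xs) {
  vapply(xs, function(X) cnn_forward(X, model, training = FALSE), numeric(1))
}

# Gradients of the cross-entropy loss -log p(y) for one sample.
# Returns list(kernels = list(dW, db), fc_W, fc_b, loss).
cnn_gradients <- function(X, y, model, dropout_mask = NULL) {
  act <- activation_fun(model$activation)
  cache <- cnn_forward_cache(unclass(X), model, dropout_mask)
  K <- length(model$kernels)
  target <- c(1 - y, y)                 # one-hot over (negative, positive)
  ds <- cache$probs - target            # d loss / d scores
  g_fcW <- tcrossprod(ds, cache$z_drop)
  g_fcb <- ds
  dz <- as.numeric(crossprod(model$fc_W, ds))
  if (!is.null(cache$mask)) dz <- dz * cache$mask
  g_kernels <- vector("list", K)
  Xm <- unclass(X)
  for (k in seq_len(K)) {
    kr <- model$kernels[[k]]
    da <- dz[k] * act$df(cache$pre_at_max[k])
    i0 <- cache$argmax[k]
    g_kernels[[k]] <- list(
      dW = da * Xm[i0:(i0 + kr$m - 1L), , drop = FALSE],
      db = da
    )
  }
  list(kernels = g_kernels, fc_W = g_fcW, fc_b = g_fcb,
       loss = -log(max(cache$probs[y + 1L], 1e-12)))
}

apply_gradients <- function(model, grads, lr, scale = 1) {
  for (k in seq_along(model$kernels)) {
    model$kernels[[k]]$W <- model$kernels[[k]]$W - lr * scale * grads$kernels[[k]]$dW
    model$kernels[[k]]$b <- model$kernels[[k]]$b - lr * scale * grads$kernels[[k]]$db
  }
  model$fc_W <- model$fc_W - lr * scale * grads$fc_W
  model$fc_b <- model$fc_b - lr * scale * grads$fc_b
  model
}

zero_like_grads <- function(model) {
  list(
    kernels = lapply(model$kernels, function(kr)
      list(dW = kr$W * 0, db = 0)),
    fc_W = model$fc_W * 0, fc_b = model$fc_b * 0, loss = 0
  )
}

add_grads <- function(a, b) {
  for (k in seq_along(a$kernels)) {
    a$kernels[[k]]$dW <- a$kernels[[k]]$dW + b$kernels[[k]]$dW
    a$kernels[[k]]$db <- a$kernels[[k]]$db + b$kernels[[k]]$db
  }
  a$fc_W <- a$fc_W + b$fc_W
  a$fc_b <- a$fc_b + b$fc_b
  a$loss <- a$loss + b$loss
  a
}

#' Train a CNN classifier by minibatch SGD
#'
#' Cross-entropy loss on 2-way softmax output; dropout applied to the pooled
#' feature vector during training; deterministic in `seed`.
#'
#' @param model A `cnn_model`.
#' @param dataset Non-empty list of `list(x = <document matrix>, y = 0/1)`.
#' @param epochs Number of passes; `NULL` uses the model's configured budget.
#'   `epochs = 0` returns the model unchanged.
#' @param seed Seed for shuffling and dropout; `NULL` uses the model's seed.
#' @return The updated `cnn_model`, with mean per-epoch training loss
#'   appended to `model$history`.
#' @export
cnn_train <- function(model, dataset, epochs = NULL, seed = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (!length(dataset)) stop("dataset is empty")
  if (is.null(epochs)) epochs <- model$config$epochs
  if (is.null(seed)) seed <- model$config$seed
  if (epochs == 0) return(model)
  lr <- model$config$lr
  bs <- model$config$batch_size
  N <- length(dataset)
  with_seed(derive_seed(seed, "cnn-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0
      for (start in seq(1L, N, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, N)]
        acc <- zero_like_grads(model)
        for (j in batch) {
          mask <- NULL
          if (model$dropout_rate > 0) {
            keep <- stats::runif(length(model$kernels)) >= model$dropout_rate
            mask <- keep / (1 - model$dropout_rate)
          }
          g <- cnn_gradients(dataset[[j]]$x, dataset[[j]]$y, model, mask)
          acc <- add_grads(acc, g)
        }
        model <- apply_gradients(model, acc, lr, scale = 1 / length(batch))
        ep_loss <- ep_loss + acc$loss
      }
      model$history <- c(model$history, ep_loss / N)
    }
    model
  })
}

#' Mean cross-entropy loss of a model on a dataset (evaluation mode)
#'
#' @param model A `cnn_model`.
#' @param dataset List of `list(x, y)` samples.
#' @return Mean `-log p(y)` over the dataset.
#' @export
cnn_loss <- function(model, dataset) {
  mean(vapply(dataset, function(s) {
    eta <- cnn_forward(s$x, model, training = FALSE)
    -log(max(if (s$y == 1) eta else 1 - eta, 1e-12))
  }, numeric(1)))
}

#' Save/load a CNN model checkpoint
#'
#' Checkpoints are plain JSON containing shapes, parameters, and training
#' config; the layout (`n`, `activation`, `dropout_rate`, `kernels[].W/b`,
#' `fc_W`, `fc_b`, `config`) is stable across package versions.
#'
#' @param model A `cnn_model`.
#' @param path File path.
#' @return `write_cnn_checkpoint()` returns `path` invisibly;
#'   `read_cnn_checkpoint()` a `cnn_model`.
#' @export
write_cnn_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  payload <- list(
    format = "nsclcstager-cnn-1",
    n = model$n, activation = model$activation,
    dropout_rate = model$dropout_rate,
    kernels = lapply(model$kernels, function(kr)
      list(m = kr$m, W = kr$W, b = kr$b)),
    fc_W = model$fc_W, fc_b = model$fc_b,
    config = model$config, history = model$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cnn_checkpoint
#' @export
read_cnn_checkpoint <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(x$format, "nsclcstager-cnn-1")) {
    stop("unrecognized checkpoint format in ", path)
  }
  kernels <- lapply(seq_along(x$kernels$m), function(i) {
    conv_kernel(as.matrix(x$kernels$W[[i]]), x$kernels$b[[i]])
  })
  fc_W <- as.matrix(x$fc_W)
  storage.mode(fc_W) <- "double"
  structure(list(
    n = as.integer(x$n), kernels = kernels, activation = x$activation,
    fc_W = fc_W,
    fc_b = as.numeric(x$fc_b),
    dropout_rate = x$dropout_rate,
    config = list(optimizer = x$config$optimizer, lr = x$config$lr,
                  batch_size = as.integer(x$config$batch_size),
                  epochs = as.integer(x$config$epochs),
                  seed = as.integer(x$config$seed)),
    history = as.numeric(x$history)
  ), class = "cnn_model")
}
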