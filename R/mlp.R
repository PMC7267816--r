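# Feed-forward multilayer perceptron, implemented from scratch: softmax
# output, multinomial cross-entropy, exact backpropagation, mini-batch SGD or
# Adam with optional early stopping. At most three hidden layers.

MLP_MAX_HIDDEN <- 3L
MODEL_FORMAT_VERSION <- 1L

#' Initialize a multilayer perceptron
#'
#' Weights are drawn uniformly from `(-1, 1) / sqrt(fan_in)` (a symmetric
#' distribution with scale `1/sqrt(fan_in)`), biases start at zero. The same
#' seed always reproduces the same model bit for bit.
#'
#' @param layer_sizes Integer vector `[input, h1 ... hk, classes]` with
#'   `1 <= k <= 3` hidden layers, all sizes positive.
#' @param activation Hidden activation: `"relu"` (default), `"logistic"` or
#'   `"tanh"`. The output layer is always softmax.
#' @param seed Integer RNG seed for the weight draw.
#' @return An `mlp_model` list with `layer_sizes`, weight matrices `W`
#'   (fan_in x fan_out), bias vectors `b`, `activation`, and empty slots for
#'   `label_map`, `render_config` and `training_history`.
#' @export
init_model <- function(layer_sizes, activation = c("relu", "logistic", "tanh"),
                       seed = 1L) {
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  n_hidden <- length(layer_sizes) - 2L
  if (n_hidden < 1L || n_hidden > MLP_MAX_HIDDEN)
    stop("the network supports 1 to ", MLP_MAX_HIDDEN, " hidden layers, got ",
         n_hidden)
  if (any(layer_sizes <= 0)) stop("all layer sizes must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(layer_sizes) - 1L)) {
    fan_in <- layer_sizes[l]
    W[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1L], -1, 1) / sqrt(fan_in),
                     nrow = fan_in, ncol = layer_sizes[l + 1L])
    b[[l]] <- numeric(layer_sizes[l + 1L])
  }
  structure(list(layer_sizes = layer_sizes, W = W, b = b,
                 activation = activation, label_map = NULL,
                 render_config = NULL, training_history = NULL),
            class = "mlp_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

act_fun <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         logistic = 1 / (1 + exp(-z)),
         tanh = tanh(z))
}

# derivative expressed through the activation value a (and pre-activation z
# for relu)
act_deriv <- function(a, z, activation) {
  switch(activation,
         relu = (z > 0) * 1,
         logistic = a * (1 - a),
         tanh = 1 - a * a)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward_cache <- function(model, X) {
  L <- length(model$W)
  A <- vector("list", L + 1L)  # activations, A[[1]] = input
  Z <- vector("list", L)       # pre-activations
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$W[[l]], 2, model$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) act_fun(Z[[l]], model$activation)
                   else softmax_rows(Z[[l]])
  }
  list(A = A, Z = Z)
}

#' Forward pass: class probabilities for a batch of images
#'
#' @param model An `mlp_model`.
#' @param X Numeric matrix, one flattened image per row; the row length must
#'   equal the model's input layer size.
#' @return Matrix of softmax class probabilities, rows summing to 1.
#' @export
mlp_forward <- function(model, X) {
  X <- as_input_matrix(model, X)
  mlp_forward_cache(model, X)$A[[length(model$W) + 1L]]
}

as_input_matrix <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$layer_sizes[1])
    stop("input has ", ncol(X), " features but the model expects ",
         model$layer_sizes[1])
  X
}

#' Mean cross-entropy loss in nats
#'
#' `-mean(log p[true class])`, with probabilities clipped below 1e-15 so a
#' confident wrong prediction cannot produce `-log(0)`.
#'
#' @param probs Probability matrix (rows are distributions).
#' @param labels Integer class labels, 1-based, one per row.
#' @return Non-negative scalar.
#' @export
mlp_loss <- function(probs, labels) {
  stopifnot(nrow(probs) == length(labels), all(labels >= 1),
            all(labels <= ncol(probs)))
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  mean(-log(pmax(p, 1e-15)))
}

one_hot <- function(labels, C) {
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Exact gradients of the regularized cross-entropy loss
#'
#' Backpropagation through softmax + cross-entropy; an L2 penalty
#' `l2/2 * sum(W^2)` on the weights (not the biases) adds `l2 * W` to each
#' weight gradient.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix (one sample per row).
#' @param labels 1-based integer class labels.
#' @param l2 L2 penalty strength.
#' @return List with gradient lists `dW` and `db` shaped like `model$W`,
#'   `model$b`, plus the batch `loss` (data term only).
#' @export
mlp_gradients <- function(model, X, labels, l2 = 0) {
  X <- as_input_matrix(model, X)
  L <- length(model$W)
  n <- nrow(X)
  cache <- mlp_forward_cache(model, X)
  probs <- cache$A[[L + 1L]]
  Y <- one_hot(labels, ncol(probs))
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (probs - Y) / n
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta) + l2 * model$W[[l]]
    db[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(model$W[[l]])) *
        act_deriv(cache$A[[l]], cache$Z[[l - 1L]], model$activation)
  }
  list(dW = dW, db = db, loss = mlp_loss(probs, labels))
}

#' Training configuration
#'
#' Defaults mirror the common choices for small image classifiers: Adam
#' (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), learning rate 1e-3,
#' mini-batches of 32, at most 200 epochs, early stopping with patience 10
#' and tolerance 1e-4 on an internal validation split, L2 penalty 1e-4.
#'
#' @param learning_rate Step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param patience Early-stopping patience in epochs; `Inf` disables early
#'   stopping.
#' @param tolerance Minimum loss improvement that resets the patience counter.
#' @param l2 L2 penalty on weights.
#' @param validation_fraction Fraction of the training samples held out for
#'   early stopping (0 makes early stopping watch the training loss).
#' @param seed Seed fixing initialization, the validation split and batch
#'   order.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 200L, optimizer = c("adam", "sgd"),
                         patience = 10L, tolerance = 1e-4, l2 = 1e-4,
                         validation_fraction = 0.1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, tolerance > 0, l2 >= 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 patience = patience, tolerance = tolerance, l2 = l2,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a multilayer perceptron
#'
#' Mini-batch optimization of softmax cross-entropy with seeded shuffling.
#' When early stopping is active, a seeded random `validation_fraction` of
#' the samples is held out; training stops once the validation loss has not
#' improved by at least `tolerance` for `patience` consecutive epochs, and
#' the parameters from the best validation epoch are restored. Training is a
#' pure function of (data, architecture, config): reruns are identical.
#'
#' @param X Input matrix, one flattened image per row.
#' @param labels 1-based integer class labels.
#' @param hidden Integer vector of 1-3 hidden layer sizes.
#' @param tcfg A [train_config()].
#' @param activation Hidden activation passed to [init_model()].
#' @return A trained `mlp_model`; `training_history` is a data.frame with
#'   one row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @export
mlp_train <- function(X, labels, hidden = c(100L), tcfg = train_config(),
                      activation = "relu") {
  if (is.null(dim(X)) || nrow(X) == 0) stop("empty training set")
  labels <- as.integer(labels)
  C <- max(labels)
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 classes, got ", length(unique(labels)))
  layer_sizes <- c(ncol(X), as.integer(hidden), C)
  model <- init_model(layer_sizes, activation = activation, seed = tcfg$seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tcfg$seed + 1L)

  n <- nrow(X)
  use_val <- is.finite(tcfg$patience) && tcfg$validation_fraction > 0 &&
    floor(n * tcfg$validation_fraction) >= 1
  if (use_val) {
    n_val <- max(1L, floor(n * tcfg$validation_fraction))
    val_idx <- sample.int(n, n_val)
    Xv <- X[val_idx, , drop = FALSE]; yv <- labels[val_idx]
    Xt <- X[-val_idx, , drop = FALSE]; yt <- labels[-val_idx]
  } else {
    Xt <- X; yt <- labels; Xv <- NULL; yv <- NULL
  }
  nt <- nrow(Xt)

  # Adam moment estimates
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf; best_model <- NULL; stall <- 0L

  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(nt)
    for (start in seq.int(1L, nt, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1L, nt)]
      g <- mlp_gradients(model, Xt[idx, , drop = FALSE], yt[idx], l2 = tcfg$l2)
      step <- step + 1L
      for (l in seq_along(model$W)) {
        if (tcfg$optimizer == "adam") {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$db[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$db[[l]]^2
          mhatW <- mW[[l]] / (1 - beta1^step)
          vhatW <- vW[[l]] / (1 - beta2^step)
          mhatb <- mb[[l]] / (1 - beta1^step)
          vhatb <- vb[[l]] / (1 - beta2^step)
          model$W[[l]] <- model$W[[l]] - tcfg$learning_rate * mhatW / (sqrt(vhatW) + eps)
          model$b[[l]] <- model$b[[l]] - tcfg$learning_rate * mhatb / (sqrt(vhatb) + eps)
        } else {
          model$W[[l]] <- model$W[[l]] - tcfg$learning_rate * g$dW[[l]]
          model$b[[l]] <- model$b[[l]] - tcfg$learning_rate * g$db[[l]]
        }
      }
    }
    train_loss <- mlp_loss(mlp_forward(model, Xt), yt)
    val_loss <- if (use_val) mlp_loss(mlp_forward(model, Xv), yv) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (is.finite(tcfg$patience)) {
      watched <- if (use_val) val_loss else train_loss
      if (watched < best_loss - tcfg$tolerance) {
        best_loss <- watched
        best_model <- list(W = model$W, b = model$b)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
  }
  if (is.finite(tcfg$patience) && !is.null(best_model)) {
    model$W <- best_model$W
    model$b <- best_model$b
  }
  model$training_history <- history
  model
}

#' Predict classes for a batch of images
#'
#' Argmax of the forward pass; ties break toward the lowest class index.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix.
#' @return List with `class` (1-based integer indices) and `probability`
#'   (winning softmax probability per sample).
#' @export
mlp_predict <- function(model, X) {
  probs <- mlp_forward(model, X)
  cls <- max.col(probs, ties.method = "first")
  list(class = cls, probability = probs[cbind(seq_len(nrow(probs)), cls)])
}

#' Save a model bundle
#'
#' One portable HDF5 container: weight matrices `W0...Wk` and bias vectors
#' `b0...bk` as float64 datasets, plus a YAML `header` string holding
#' `layer_sizes`, `activation`, `label_map`, `render_config` and the format
#' version, and the training history as a dataset. Loading reproduces the
#' forward pass bit for bit.
#'
#' @param model An `mlp_model` (ideally with `label_map` and `render_config`
#'   set, so inference can check its inputs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  h5_create_file_(path)
  for (l in seq_along(model$W)) {
    W <- model$W[[l]]
    h5_write_array_(path, paste0("W", l - 1L), as.numeric(t(W)), dim(W))
    h5_write_array_(path, paste0("b", l - 1L), model$b[[l]], length(model$b[[l]]))
  }
  if (!is.null(model$training_history) && nrow(model$training_history) > 0) {
    H <- as.matrix(model$training_history)
    h5_write_array_(path, "training_history", as.numeric(t(H)), dim(H))
  }
  header <- list(format_version = MODEL_FORMAT_VERSION,
                 layer_sizes = as.integer(model$layer_sizes),
                 activation = model$activation,
                 label_map = if (is.null(model$label_map)) NULL
                             else as.list(model$label_map),
                 render_config = if (is.null(model$render_config)) NULL
                                 else unclass(model$render_config))
  h5_write_string_(path, "header", yaml::as.yaml(header))
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Path written by [save_model()].
#' @return The restored `mlp_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (!h5_has_dataset_(path, "header"))
    stop("not a model bundle (no 'header' dataset): ", path)
  header <- yaml::yaml.load(h5_read_string_(path, "header"))
  if (is.null(header$format_version) ||
      header$format_version != MODEL_FORMAT_VERSION)
    stop("unsupported model format version: ",
         header$format_version %||% "<missing>")
  for (field in c("layer_sizes", "activation", "label_map"))
    if (is.null(header[[field]]))
      stop("model bundle is missing required field '", field, "'")
  layer_sizes <- as.integer(header$layer_sizes)
  L <- length(layer_sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    wd <- h5_read_array_(path, paste0("W", l - 1L))
    W[[l]] <- matrix(wd$data, nrow = wd$dims[1], ncol = wd$dims[2], byrow = TRUE)
    b[[l]] <- h5_read_array_(path, paste0("b", l - 1L))$data
  }
  history <- NULL
  if (h5_has_dataset_(path, "training_history")) {
    hd <- h5_read_array_(path, "training_history")
    H <- matrix(hd$data, nrow = hd$dims[1], ncol = hd$dims[2], byrow = TRUE)
    history <- data.frame(epoch = as.integer(H[, 1]), train_loss = H[, 2],
                          val_loss = H[, 3])
  }
  rc <- NULL
  if (!is.null(header$render_config)) {
    rc <- render_config(oversampling = header$render_config$oversampling,
                        image_size = header$render_config$image_size,
                        centering = header$render_config$centering,
                        normalization = header$render_config$normalization)
  }
  structure(list(layer_sizes = layer_sizes, W = W, b = b,
                 activation = header$activation,
                 label_map = unlist(header$label_map),
                 render_config = rc, training_history = history),
            class = "mlp_model")
}
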