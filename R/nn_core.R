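# From-scratch multilayer perceptron: forward propagation, loss functions,
# and a mini-batch steepest-gradient trainer with learning rate, momentum,
# per-update decay, and inverted dropout.

ACTIVATIONS <- c("tanh", "sigmoid", "softmax", "linear")

apply_activation <- function(z, activation) {
  switch(activation,
    tanh    = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    linear  = z,
    softmax = {
      z <- z - apply(z, 1L, max)       # shift rows for numerical stability
      e <- exp(z)
      e / rowSums(e)
    },
    stop(sprintf("unknown activation '%s'", activation), call. = FALSE)
  )
}

#' Construct an untrained multilayer perceptron
#'
#' Builds a feedforward network with the given layer widths.  Weights are
#' initialized uniformly on (-s, s) with s = 1/sqrt(fan_in) for each layer
#' (small values around zero, scaled to the layer's fan-in); biases start at
#' zero.  The output layer is a softmax over the classes for classification
#' and a single linear neuron for regression.
#'
#' @param layer_sizes Integer vector of layer widths, from the input layer
#'   through the hidden layers to the output layer.  For classification the
#'   last entry is the number of classes; for regression it must be 1.
#' @param task `"classification"` or `"regression"`.
#' @param hidden_activation Activation for the hidden layers, `"tanh"` or
#'   `"sigmoid"`.  Defaults to tanh for classification and sigmoid for
#'   regression.
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `mlp_model`: a list with `weights` (a list of
#'   fan_in x fan_out matrices), `biases`, `hidden_activation`,
#'   `output_activation`, `task`, and `layer_sizes`.
#' @examples
#' m <- mlp_model(c(4, 8, 3), task = "classification", seed = 1)
#' dim(m$weights[[1]])
#' @export
mlp_model <- function(layer_sizes,
                      task = c("classification", "regression"),
                      hidden_activation = NULL,
                      seed = 1L) {
  task <- match.arg(task)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("'layer_sizes' needs at least input and output widths, all >= 1",
         call. = FALSE)
  }
  if (task == "regression" && layer_sizes[length(layer_sizes)] != 1L) {
    stop("regression networks must have exactly 1 output neuron",
         call. = FALSE)
  }
  if (is.null(hidden_activation)) {
    hidden_activation <- if (task == "classification") "tanh" else "sigmoid"
  }
  hidden_activation <- match.arg(hidden_activation, c("tanh", "sigmoid"))
  output_activation <- if (task == "classification") "softmax" else "linear"

  n_layers <- length(layer_sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  with_seed(seed, {
    for (k in seq_len(n_layers)) {
      fan_in <- layer_sizes[k]
      fan_out <- layer_sizes[k + 1L]
      s <- 1 / sqrt(fan_in)
      weights[[k]] <- matrix(stats::runif(fan_in * fan_out, -s, s),
                             nrow = fan_in, ncol = fan_out)
      biases[[k]] <- numeric(fan_out)
    }
  })
  structure(
    list(weights = weights, biases = biases,
         hidden_activation = hidden_activation,
         output_activation = output_activation,
         task = task, layer_sizes = layer_sizes),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Multilayer perceptron (%s): %s, hidden %s, output %s\n",
              x$task, paste(x$layer_sizes, collapse = "-"),
              x$hidden_activation, x$output_activation))
  invisible(x)
}

#' Single-layer forward propagation
#'
#' Computes `activation(inputs %*% weights + biases)`: each neuron sums its
#' inputs against its weight column, adds its bias, and passes the sum
#' through the nonlinearity.
#'
#' @param inputs Numeric vector (one sample) or matrix (samples x fan_in).
#' @param weights Numeric matrix, fan_in x fan_out.
#' @param biases Numeric vector of length fan_out.
#' @param activation One of `"tanh"`, `"sigmoid"`, `"softmax"`, `"linear"`.
#' @param layer Optional layer label used in dimension-mismatch errors.
#' @return Numeric matrix of activations, samples x fan_out.
#' @examples
#' forward_layer(c(1, 1), matrix(c(0.5, 0.5)), 0, "tanh")  # tanh(1)
#' @export
forward_layer <- function(inputs, weights, biases, activation, layer = NULL) {
  inputs <- as_feature_matrix(inputs)
  weights <- as.matrix(weights)
  activation <- match.arg(activation, ACTIVATIONS)
  if (ncol(inputs) != nrow(weights)) {
    where <- if (is.null(layer)) "" else sprintf(" at layer %s", layer)
    stop(sprintf(
      "shape mismatch%s: %d input features but weight fan-in is %d",
      where, ncol(inputs), nrow(weights)), call. = FALSE)
  }
  if (length(biases) != ncol(weights)) {
    stop("length of 'biases' must equal the weight fan-out", call. = FALSE)
  }
  z <- sweep(inputs %*% weights, 2L, biases, "+")
  apply_activation(z, activation)
}

#' Mean squared error between targets and predictions
#'
#' Two variants of the squared-residual cost over n samples, where each
#' residual row is dotted with itself: `eq2_mean` averages the row dot
#' products (the usual MSE used here as the regression cost), and
#' `eq3_half_sum` is half the plain sum (the classical back-propagation
#' cost whose gradient drops the factor 2).
#'
#' @param actual,predicted Numeric vectors or matrices of identical shape;
#'   rows are samples.
#' @param variant `"eq2_mean"` or `"eq3_half_sum"`.
#' @return A non-negative scalar.
#' @examples
#' mse(c(1, 0), c(0, 0))                       # 0.5 under eq2_mean
#' mse(matrix(c(1, 0), 1), matrix(0, 1, 2))    # 1.0: one sample, dot = 1
#' @export
mse <- function(actual, predicted, variant = c("eq2_mean", "eq3_half_sum")) {
  variant <- match.arg(variant)
  actual <- as_feature_matrix(actual)
  predicted <- as_feature_matrix(predicted)
  if (!identical(dim(actual), dim(predicted))) {
    stop("'actual' and 'predicted' must have identical shapes", call. = FALSE)
  }
  if (nrow(actual) < 1L || length(actual) == 0L) {
    stop("empty input", call. = FALSE)
  }
  row_dots <- rowSums((actual - predicted)^2)
  switch(variant,
         eq2_mean = mean(row_dots),
         eq3_half_sum = sum(row_dots) / 2)
}

#' Negative log-likelihood of true classes
#'
#' Mean over samples of `-log p(true class)` given a matrix of per-class
#' probabilities.  Probabilities are clamped at 1e-12 below before the log so
#' a confident wrong prediction yields a large but finite loss.
#'
#' @param class_probabilities Numeric matrix, samples x classes, rows summing
#'   to one.
#' @param true_labels Integer vector of 1-based class indices.
#' @return A non-negative scalar.
#' @examples
#' nll_loss(matrix(c(0.5, 0.5), 1), 1L)  # log(2)
#' @export
nll_loss <- function(class_probabilities, true_labels) {
  p <- as_feature_matrix(class_probabilities)
  true_labels <- as.integer(true_labels)
  if (length(true_labels) != nrow(p)) {
    stop("one label per probability row is required", call. = FALSE)
  }
  if (any(true_labels < 1L | true_labels > ncol(p))) {
    stop(sprintf("label index out of range 1..%d", ncol(p)), call. = FALSE)
  }
  picked <- p[cbind(seq_len(nrow(p)), true_labels)]
  mean(-log(pmax(picked, 1e-12)))
}

#' Training hyperparameters for the mini-batch gradient trainer
#'
#' @param learning_rate Non-negative base learning rate (zero gives a
#'   no-op trainer).
#' @param momentum Momentum coefficient in [0, 1).
#' @param decay Non-negative per-update learning-rate decay: the effective
#'   rate for update u (counting from 0) is `learning_rate / (1 + decay * u)`.
#' @param dropout_rate Probability in [0, 1) of dropping a hidden activation
#'   during training (inverted dropout: kept units are scaled by 1/(1-p)).
#' @param epochs Number of passes over the training data (0 allowed: no-op).
#' @param batch_size Mini-batch size; the last partial batch of an epoch is
#'   used as-is so every epoch sees all samples.
#' @param seed Integer seed controlling shuffling and dropout masks.
#' @return An object of class `train_settings`.
#' @export
train_settings <- function(learning_rate = 0.1, momentum = 0.0, decay = 0.0,
                           dropout_rate = 0.0, epochs = 10L,
                           batch_size = 32L, seed = 1L) {
  stopifnot_scalar_number(learning_rate, "learning_rate")
  if (learning_rate < 0) stop("'learning_rate' must be >= 0", call. = FALSE)
  stopifnot_scalar_number(momentum, "momentum", 0, 1 - 1e-12)
  stopifnot_scalar_number(decay, "decay", 0)
  stopifnot_scalar_number(dropout_rate, "dropout_rate", 0, 1 - 1e-12)
  epochs <- as.integer(epochs)
  if (length(epochs) != 1L || is.na(epochs) || epochs < 0L) {
    stop("'epochs' must be a non-negative integer", call. = FALSE)
  }
  batch_size <- as.integer(batch_size)
  if (length(batch_size) != 1L || is.na(batch_size) || batch_size < 1L) {
    stop("'batch_size' must be a positive integer", call. = FALSE)
  }
  structure(
    list(learning_rate = learning_rate, momentum = momentum, decay = decay,
         dropout_rate = dropout_rate, epochs = epochs,
         batch_size = batch_size, seed = as.integer(seed)),
    class = "train_settings"
  )
}

# Forward pass through all layers.  When training, hidden activations get an
# inverted-dropout mask drawn from the current RNG stream; masks are returned
# so back-propagation can reuse them.
mlp_forward <- function(model, x, dropout_rate = 0, training = FALSE) {
  n_layers <- length(model$weights)
  activations <- vector("list", n_layers + 1L)
  masks <- vector("list", n_layers)
  activations[[1L]] <- x
  for (k in seq_len(n_layers)) {
    act <- if (k < n_layers) model$hidden_activation else model$output_activation
    a <- forward_layer(activations[[k]], model$weights[[k]],
                       model$biases[[k]], act, layer = k)
    if (training && dropout_rate > 0 && k < n_layers) {
      keep <- matrix(
        stats::runif(length(a)) >= dropout_rate,
        nrow = nrow(a)
      )
      a <- a * keep / (1 - dropout_rate)
      masks[[k]] <- keep
    }
    activations[[k + 1L]] <- a
  }
  list(activations = activations, masks = masks)
}

# Training loss and parameter gradients for one mini-batch.
# Classification: softmax output + mean negative log-likelihood, so the
# output-layer error is (P - Y)/n.  Regression: linear output + mean squared
# error, error 2*(P - Y)/n.
mlp_gradients <- function(model, x, y, dropout_rate = 0, training = TRUE) {
  n <- nrow(x)
  fwd <- mlp_forward(model, x, dropout_rate, training = training)
  acts <- fwd$activations
  n_layers <- length(model$weights)
  out <- acts[[n_layers + 1L]]

  if (model$task == "classification") {
    loss <- nll_loss(out, max.col(y, ties.method = "first"))
    delta <- (out - y) / n
  } else {
    loss <- mse(y, out, "eq2_mean")
    delta <- 2 * (out - y) / n
  }

  grads_w <- vector("list", n_layers)
  grads_b <- vector("list", n_layers)
  for (k in rev(seq_len(n_layers))) {
    grads_w[[k]] <- crossprod(acts[[k]], delta)
    grads_b[[k]] <- colSums(delta)
    if (k > 1L) {
      back <- delta %*% t(model$weights[[k]])
      a_prev <- acts[[k]]
      dact <- if (model$hidden_activation == "tanh") 1 - a_prev^2
              else a_prev * (1 - a_prev)
      if (!is.null(fwd$masks[[k - 1L]])) {
        # the mask (with its 1/(1-p) scale) multiplies both forward and
        # backward signals; a_prev already carries the scale, so derivative
        # terms must be taken on the pre-mask activation
        keep <- fwd$masks[[k - 1L]]
        scale <- keep / (1 - dropout_rate)
        a_raw <- ifelse(scale > 0, a_prev / ifelse(scale > 0, scale, 1), 0)
        dact <- if (model$hidden_activation == "tanh") 1 - a_raw^2
                else a_raw * (1 - a_raw)
        back <- back * scale
      }
      delta <- back * dact
    }
  }
  list(loss = loss, grads_w = grads_w, grads_b = grads_b)
}

labels_to_onehot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > n_classes)) {
    stop(sprintf("class labels must lie in 1..%d", n_classes), call. = FALSE)
  }
  y <- matrix(0, nrow = length(labels), ncol = n_classes)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Train a network by mini-batch momentum gradient descent
#'
#' Steepest-descent training with the legacy momentum/decay rule: for each
#' mini-batch, `v <- momentum * v - lr_u * grad` and `w <- w + v`, where
#' `lr_u = learning_rate / (1 + decay * u)` and u counts updates from 0.
#' Hidden layers use inverted dropout during training only.  Identical seed
#' and inputs give bitwise-identical results.
#'
#' @param model An [mlp_model()].
#' @param features Numeric matrix, samples x input width, expected on a unit
#'   scale (see [scale_unit()]).
#' @param targets For classification, either 1-based integer class labels or
#'   a one-hot matrix; for regression, a numeric vector or 1-column matrix.
#' @param settings A [train_settings()] object.
#' @return A list with `model` (the trained network) and `history`, a
#'   `loss_history` object holding `per_epoch_loss` (mean per-sample training
#'   loss of each epoch), `final_loss`, and a `diverged` flag.  If a
#'   non-finite loss appears, training stops at that epoch and `diverged` is
#'   `TRUE`.
#' @examples
#' d <- make_classification_data(60, 4, 2, separation = 4, seed = 1)
#' m <- mlp_model(c(4, 8, 2), "classification", seed = 1)
#' fit <- sgd_train(m, d$features, d$labels,
#'                  train_settings(epochs = 5, seed = 1))
#' fit$history$final_loss < fit$history$per_epoch_loss[1]
#' @export
sgd_train <- function(model, features, targets, settings) {
  stopifnot(inherits(model, "mlp_model"), inherits(settings, "train_settings"))
  x <- as_feature_matrix(features)
  n <- nrow(x)
  in_width <- model$layer_sizes[1L]
  out_width <- model$layer_sizes[length(model$layer_sizes)]
  if (ncol(x) != in_width) {
    stop(sprintf("feature width %d does not match input layer width %d",
                 ncol(x), in_width), call. = FALSE)
  }
  y <- if (model$task == "classification") {
    if (is.matrix(targets)) as_feature_matrix(targets)
    else labels_to_onehot(targets, out_width)
  } else {
    as_feature_matrix(as.numeric(targets))
  }
  if (model$task == "regression" && ncol(y) == n && nrow(y) == 1L) y <- t(y)
  if (nrow(y) != n) stop("'targets' length must match rows of 'features'",
                         call. = FALSE)

  history <- list(per_epoch_loss = numeric(0), final_loss = NA_real_,
                  diverged = FALSE)
  class(history) <- "loss_history"
  if (settings$epochs == 0L) {
    return(list(model = model, history = history))
  }

  batch_size <- min(settings$batch_size, n)
  velocity_w <- lapply(model$weights, function(w) array(0, dim(w)))
  velocity_b <- lapply(model$biases, function(b) numeric(length(b)))
  update_count <- 0L

  with_seed(settings$seed, {
    for (epoch in seq_len(settings$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      epoch_loss_sum <- 0
      for (s in starts) {
        batch <- idx[s:min(s + batch_size - 1L, n)]
        g <- mlp_gradients(model, x[batch, , drop = FALSE],
                           y[batch, , drop = FALSE],
                           dropout_rate = settings$dropout_rate,
                           training = TRUE)
        if (!is.finite(g$loss)) {
          history$per_epoch_loss <- c(history$per_epoch_loss, g$loss)
          history$final_loss <- g$loss
          history$diverged <- TRUE
          return(list(model = model, history = history))
        }
        epoch_loss_sum <- epoch_loss_sum + g$loss * length(batch)
        lr_u <- settings$learning_rate / (1 + settings$decay * update_count)
        for (k in seq_along(model$weights)) {
          velocity_w[[k]] <- settings$momentum * velocity_w[[k]] -
            lr_u * g$grads_w[[k]]
          velocity_b[[k]] <- settings$momentum * velocity_b[[k]] -
            lr_u * g$grads_b[[k]]
          model$weights[[k]] <- model$weights[[k]] + velocity_w[[k]]
          model$biases[[k]] <- model$biases[[k]] + velocity_b[[k]]
        }
        update_count <- update_count + 1L
      }
      history$per_epoch_loss <- c(history$per_epoch_loss, epoch_loss_sum / n)
    }
    history$final_loss <-
      history$per_epoch_loss[length(history$per_epoch_loss)]
    list(model = model, history = history)
  })
}

#' Predict from a trained network
#'
#' Forward propagation with dropout disabled.  For classification the label
#' is the class with the largest output score (argmax); for regression the
#' scalar network outputs are returned.
#'
#' @param object An [mlp_model()].
#' @param newdata Numeric feature matrix with the input layer's width.
#' @param ... Unused.
#' @return For classification, a list with `scores` (samples x classes
#'   softmax matrix) and `labels` (1-based argmax indices); for regression, a
#'   list with `values` (numeric vector).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$layer_sizes[1L]) {
    stop(sprintf("feature width %d does not match input layer width %d",
                 ncol(x), object$layer_sizes[1L]), call. = FALSE)
  }
  out <- mlp_forward(object, x, dropout_rate = 0, training = FALSE)
  scores <- out$activations[[length(out$activations)]]
  if (object$task == "classification") {
    list(scores = scores, labels = max.col(scores, ties.method = "first"))
  } else {
    list(values = as.numeric(scores))
  }
}

#' Serialize a network (with its training settings) to a JSON archive
#'
#' Writes layer shapes, weights, biases, activation and task enums, and the
#' training settings to a single JSON file at full double precision, so the
#' archive round-trips bit-exactly through [read_mlp()].
#'
#' @param model An [mlp_model()].
#' @param path Output file path.
#' @param settings Optional [train_settings()] stored alongside the model.
#' @return `path`, invisibly.
#' @export
write_mlp <- function(model, path, settings = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  payload <- list(
    format = "pswarmnet-mlp",
    version = 1L,
    layer_sizes = model$layer_sizes,
    task = model$task,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    weights = lapply(model$weights, function(w) unname(as.vector(w))),
    biases = lapply(model$biases, unname),
    train_settings = if (is.null(settings)) NULL else unclass(settings)
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a network archive written by [write_mlp()]
#'
#' @param path Path to the JSON archive.
#' @return A list with `model` (an `mlp_model`) and `settings` (a
#'   `train_settings` object or `NULL`).
#' @export
read_mlp <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "pswarmnet-mlp")) {
    stop("not a pswarmnet model archive", call. = FALSE)
  }
  sizes <- as.integer(payload$layer_sizes)
  n_layers <- length(sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  wlist <- payload$weights
  blist <- payload$biases
  for (k in seq_len(n_layers)) {
    weights[[k]] <- matrix(as.numeric(wlist[[k]]),
                           nrow = sizes[k], ncol = sizes[k + 1L])
    biases[[k]] <- as.numeric(blist[[k]])
  }
  model <- structure(
    list(weights = weights, biases = biases,
         hidden_activation = payload$hidden_activation,
         output_activation = payload$output_activation,
         task = payload$task, layer_sizes = sizes),
    class = "mlp_model"
  )
  settings <- NULL
  if (!is.null(payload$train_settings) &&
      length(payload$train_settings) > 0L) {
    ts <- payload$train_settings
    settings <- train_settings(ts$learning_rate, ts$momentum, ts$decay,
                               ts$dropout_rate, ts$epochs, ts$batch_size,
                               ts$seed)
  }
  list(model = model, settings = settings)
}
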