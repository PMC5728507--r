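# Shared fixtures and independent oracles for the test suite.

# Small, well-separated two-class problem the trainer must learn quickly.
separable_fixture <- function(n = 200, d = 6, seed = 1) {
  make_classification_data(n, d, n_classes = 2, separation = 5, seed = seed)
}

# Central finite-difference gradient of the training loss with respect to
# every weight and bias — the independent oracle for back-propagation.
numeric_gradients <- function(model, x, y, h = 1e-5) {
  loss_at <- function(m) mlp_gradients(m, x, y, dropout_rate = 0,
                                       training = FALSE)$loss
  grads_w <- lapply(model$weights, function(w) array(NA_real_, dim(w)))
  grads_b <- lapply(model$biases, function(b) numeric(length(b)))
  for (k in seq_along(model$weights)) {
    for (j in seq_along(model$weights[[k]])) {
      up <- model; up$weights[[k]][j] <- up$weights[[k]][j] + h
      dn <- model; dn$weights[[k]][j] <- dn$weights[[k]][j] - h
      grads_w[[k]][j] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
    for (j in seq_along(model$biases[[k]])) {
      up <- model; up$biases[[k]][j] <- up$biases[[k]][j] + h
      dn <- model; dn$biases[[k]][j] <- dn$biases[[k]][j] - h
      grads_b[[k]][j] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
  }
  list(grads_w = grads_w, grads_b = grads_b)
}

max_relative_gradient_error <- function(model, x, y) {
  analytic <- mlp_gradients(model, x, y, dropout_rate = 0, training = TRUE)
  numeric <- numeric_gradients(model, x, y)
  all_a <- c(unlist(analytic$grads_w), unlist(analytic$grads_b))
  all_n <- c(unlist(numeric$grads_w), unlist(numeric$grads_b))
  max(abs(all_a - all_n)) / max(abs(all_n), 1)
}

# A classifier whose softmax output is constant in the inputs: zero weights
# and a bias vector chosen by the test.  Used to build ensembles with
# hand-controlled votes.
constant_vote_classifier <- function(d, biases, score = 0.5) {
  stopifnot(length(biases) >= 2)
  m <- mlp_model(c(d, length(biases)), task = "classification", seed = 1)
  m$weights[[1]][] <- 0
  m$biases[[1]] <- biases
  m$hidden_activation <- "tanh"
  pswarmnet:::new_scored_classifier(
    m, decode_particle(search_space(hidden_layers = 1)$lower,
                       search_space(hidden_layers = 1)),
    score)
}

# A regression "network" that always predicts a constant value.
constant_value_regressor <- function(d, value, score = 0) {
  m <- mlp_model(c(d, 1), task = "regression", seed = 1)
  m$weights[[1]][] <- 0
  m$biases[[1]] <- value
  pswarmnet:::new_scored_classifier(
    m, decode_particle(search_space(hidden_layers = 1)$lower,
                       search_space(hidden_layers = 1)),
    score)
}

desk_space <- function() {
  search_space(learning_rate = c(0.01, 0.9), dropout = c(0, 0.5),
               momentum = c(0, 0.9), decay = c(1e-5, 1e-4),
               hidden_layers = 2, neurons = c(4, 24))
}
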