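test_that("forward_layer evaluates the neuron activation", {
  # tanh of a zero pre-activation is zero, whatever the inputs
  out <- forward_layer(c(1, 1), matrix(0, 2, 3), rep(0, 3), "tanh")
  expect_equal(as.numeric(out), c(0, 0, 0))

  # single tanh neuron: 1*0.5 + 1*0.5 = 1 -> (e - 1/e)/(e + 1/e)
  out <- forward_layer(c(1, 1), matrix(c(0.5, 0.5), 2, 1), 0, "tanh")
  expect_equal(as.numeric(out), 0.76159, tolerance = 1e-5)

  # sigmoid driven purely by a large bias
  out <- forward_layer(2, matrix(0, 1, 1), 10, "sigmoid")
  expect_equal(as.numeric(out), 0.9999546, tolerance = 1e-7)

  expect_error(forward_layer(c(1, 2, 3), matrix(0, 2, 1), 0, "tanh",
                             layer = 2),
               "layer 2")
})

test_that("mse implements both cost variants", {
  a <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(mse(a, a, "eq2_mean"), 0)
  expect_equal(mse(a, a, "eq3_half_sum"), 0)

  actual <- matrix(c(1, 0), 1)
  predicted <- matrix(c(0, 0), 1)
  expect_equal(mse(actual, predicted, "eq2_mean"), 1.0)
  expect_equal(mse(actual, predicted, "eq3_half_sum"), 0.5)

  expect_error(mse(matrix(0, 1, 2), matrix(0, 2, 2)), "identical shapes")
  expect_error(mse(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2)),
               "empty")
})

test_that("nll_loss is the mean negative log-probability of true classes", {
  certain <- diag(3)
  expect_equal(nll_loss(certain, 1:3), 0)
  expect_equal(nll_loss(matrix(0.5, 1, 2), 1L), log(2))
  expect_equal(nll_loss(matrix(0.1, 1, 10), 7L), log(10))
  expect_error(nll_loss(matrix(0.5, 1, 2), 3L), "out of range")
  # clamped probabilities keep a confident miss finite
  expect_true(is.finite(nll_loss(matrix(c(1, 0), 1), 2L)))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  for (task in c("classification", "regression")) {
    out_width <- if (task == "classification") 3L else 1L
    for (hidden in list(c(5L), c(4L, 3L))) {
      model <- mlp_model(c(4L, hidden, out_width), task = task,
                         seed = sample.int(1000, 1))
      x <- matrix(runif(7 * 4), 7)
      y <- if (task == "classification") {
        pswarmnet:::labels_to_onehot(sample.int(3, 7, replace = TRUE), 3L)
      } else {
        matrix(rnorm(7), 7)
      }
      expect_lt(max_relative_gradient_error(model, x, y), 1e-5)
    }
  }
})

test_that("sgd_train honors degenerate settings", {
  d <- separable_fixture(60, 4)
  model <- mlp_model(c(4, 5, 2), "classification", seed = 3)

  none <- sgd_train(model, d$features, d$targets,
                    train_settings(epochs = 0, seed = 1))
  expect_identical(none$model$weights, model$weights)
  expect_length(none$history$per_epoch_loss, 0)

  frozen <- sgd_train(model, d$features, d$targets,
                      train_settings(learning_rate = 0, epochs = 3,
                                     seed = 1))
  expect_identical(frozen$model$weights, model$weights)
  expect_length(frozen$history$per_epoch_loss, 3)
})

test_that("training is seed-deterministic and dropout 0 is exact no-dropout", {
  d <- separable_fixture(80, 5)
  model <- mlp_model(c(5, 6, 2), "classification", seed = 2)
  s <- train_settings(learning_rate = 0.2, momentum = 0.5, decay = 1e-4,
                      epochs = 6, batch_size = 16, seed = 7)
  a <- sgd_train(model, d$features, d$targets, s)
  b <- sgd_train(model, d$features, d$targets, s)
  expect_identical(a$history$per_epoch_loss, b$history$per_epoch_loss)
  expect_identical(a$model$weights, b$model$weights)

  s0 <- train_settings(learning_rate = 0.2, momentum = 0.5, decay = 1e-4,
                       dropout_rate = 0, epochs = 6, batch_size = 16,
                       seed = 7)
  c <- sgd_train(model, d$features, d$targets, s0)
  expect_identical(a$model$weights, c$model$weights)
})

test_that("training reduces loss and improves accuracy on separable data", {
  d <- separable_fixture(200, 6)
  improved <- 0L
  for (seed in 1:10) {
    model <- mlp_model(c(6, 8, 2), "classification", seed = seed)
    before <- accuracy(d$targets, predict(model, d$features)$labels)
    fit <- sgd_train(model, d$features, d$targets,
                     train_settings(learning_rate = 0.1, epochs = 20,
                                    batch_size = 32, seed = seed))
    expect_lt(fit$history$final_loss, fit$history$per_epoch_loss[1])
    after <- accuracy(d$targets, predict(fit$model, d$features)$labels)
    improved <- improved + (after > before)
  }
  expect_gte(improved, 9L)
})

test_that("divergent training is flagged, not swallowed", {
  d <- make_qsar_data(60, 6, latent_rank = 3, noise_sd = 0.05, seed = 1)
  model <- mlp_model(c(6, 5, 1), "regression", seed = 1)
  fit <- sgd_train(model, d$features, d$targets,
                   train_settings(learning_rate = 1e6, epochs = 30,
                                  seed = 1))
  expect_true(fit$history$diverged)
  expect_false(is.finite(fit$history$final_loss))
})

test_that("predict returns argmax labels and hand-checkable outputs", {
  m <- mlp_model(c(2, 3), "classification", seed = 1)
  m$weights[[1]][] <- 0
  m$biases[[1]] <- c(0.1, 0.7, 0.2)
  p <- predict(m, matrix(c(0.3, 0.4), 1))
  expect_identical(p$labels, 2L)

  # hand-built linear regression map: y = x w + b
  r <- mlp_model(c(3, 1), "regression", seed = 1)
  r$weights[[1]] <- matrix(c(1, -2, 0.5), 3)
  r$biases[[1]] <- 0.25
  x <- matrix(runif(12), 4)
  expect_equal(predict(r, x)$values, as.numeric(x %*% r$weights[[1]] + 0.25))

  expect_error(predict(r, matrix(0, 2, 5)), "width")
})

test_that("same input twice gives identical predictions", {
  d <- separable_fixture(40, 4)
  m <- mlp_model(c(4, 6, 2), "classification", seed = 9)
  expect_identical(predict(m, d$features), predict(m, d$features))
})

test_that("model archives round-trip bit-exactly", {
  d <- separable_fixture(60, 4)
  fit <- sgd_train(mlp_model(c(4, 5, 2), "classification", seed = 5),
                   d$features, d$targets,
                   train_settings(epochs = 3, momentum = 0.3, seed = 5))
  path <- tempfile(fileext = ".json")
  write_mlp(fit$model, path,
            settings = train_settings(epochs = 3, momentum = 0.3, seed = 5))
  back <- read_mlp(path)
  expect_identical(back$model$weights, fit$model$weights)
  expect_identical(back$model$biases, fit$model$biases)
  expect_identical(back$model$task, fit$model$task)
  expect_equal(back$settings$momentum, 0.3)
})
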