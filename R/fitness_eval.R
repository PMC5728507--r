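# Scoring of candidate network configurations: split the training data once
# by the lambda fraction, train briefly with a candidate's hyperparameters,
# and score on the held-out validation subset.  Maximization convention:
# classification scores are validation accuracies, regression scores are
# negated validation MSEs.

#' Evaluation protocol for scoring candidate configurations
#'
#' @param lambda Fraction of the training data kept for inner training; the
#'   complement is the validation subset that scores candidates.  Default
#'   0.8.
#' @param eval_epochs Small epoch budget used while scoring swarm particles.
#' @param final_epochs Larger epoch budget used when retraining the final
#'   candidate models; must be >= `eval_epochs`.
#' @param batch_size Mini-batch size for both phases.
#' @param task `"classification"` or `"regression"`.
#' @param fitness_metric `"validation"` (score on the held-out subset — the
#'   default) or `"training_loss"` (negated final training loss).
#' @param split_seed Seed for the lambda split.
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(lambda = 0.8, eval_epochs = 5L, final_epochs = 20L,
                          batch_size = 100L,
                          task = c("classification", "regression"),
                          fitness_metric = c("validation", "training_loss"),
                          split_seed = 1L) {
  task <- match.arg(task)
  fitness_metric <- match.arg(fitness_metric)
  stopifnot_scalar_number(lambda, "lambda")
  if (lambda <= 0 || lambda >= 1) stop("'lambda' must be in (0, 1)",
                                       call. = FALSE)
  eval_epochs <- as.integer(eval_epochs)
  final_epochs <- as.integer(final_epochs)
  if (eval_epochs < 1L) stop("'eval_epochs' must be >= 1", call. = FALSE)
  if (final_epochs < eval_epochs) {
    stop("'final_epochs' must be >= 'eval_epochs'", call. = FALSE)
  }
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("'batch_size' must be >= 1", call. = FALSE)
  structure(
    list(lambda = lambda, eval_epochs = eval_epochs,
         final_epochs = final_epochs, batch_size = batch_size, task = task,
         fitness_metric = fitness_metric,
         split_seed = as.integer(split_seed)),
    class = "eval_protocol"
  )
}

#' Split data into inner training and validation subsets
#'
#' Partitions `1..n` into a training subset of exactly `floor(lambda * n)`
#' indices and its complement.  Classification splits are stratified: each
#' class contributes proportionally (largest-remainder allocation), and an
#' error is raised if any class would be absent from the training subset.
#'
#' @param targets Class labels (classification) or numeric targets
#'   (regression); only its length and, for classification, its values are
#'   used.
#' @param lambda Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param task `"classification"` or `"regression"`.
#' @return A list with integer index vectors `train` and `val`; disjoint,
#'   union `1..n`.
#' @examples
#' s <- split_train_val(rep(1:2, 50), 0.8, seed = 1)
#' lengths(s)   # 80 and 20
#' @export
split_train_val <- function(targets, lambda, seed = 1L,
                            task = c("classification", "regression")) {
  task <- match.arg(task)
  n <- length(targets)
  if (n < 2L) stop("dataset must have at least 2 records", call. = FALSE)
  if (lambda <= 0 || lambda >= 1) stop("'lambda' must be in (0, 1)",
                                       call. = FALSE)
  n_train <- floor(lambda * n)
  if (n_train < 1L || n_train >= n) {
    stop("'lambda' leaves an empty training or validation subset",
         call. = FALSE)
  }
  with_seed(seed, {
    if (task == "regression") {
      train <- sort(sample.int(n, n_train))
    } else {
      classes <- split(seq_len(n), targets)
      # largest-remainder allocation so the training sizes sum to n_train
      exact <- vapply(classes, length, integer(1)) * lambda
      base <- floor(exact)
      shortfall <- n_train - sum(base)
      if (shortfall > 0) {
        top_up <- order(exact - base, decreasing = TRUE)[seq_len(shortfall)]
        base[top_up] <- base[top_up] + 1L
      } else if (shortfall < 0) {
        take <- order(exact - base)[seq_len(-shortfall)]
        base[take] <- base[take] - 1L
      }
      if (any(base < 1L)) {
        stop("a class would be absent from the training subset; increase lambda or the class size",
             call. = FALSE)
      }
      train <- sort(unlist(Map(function(idx, m) sample(idx, m),
                               classes, base), use.names = FALSE))
    }
    list(train = train, val = setdiff(seq_len(n), train))
  })
}

#' Score one network configuration
#'
#' Builds a fresh network from the configuration (input width from the
#' training features, hidden widths from the configuration, output width =
#' number of classes or 1), trains it for `eval_epochs` with the
#' configuration's hyperparameters on the inner training subset, and scores
#' it on the validation subset: accuracy for classification, negated MSE for
#' regression (both maximized).  A divergent training run scores `-Inf`.
#'
#' @param config A `network_config`.
#' @param x_train,y_train Inner training subset.
#' @param x_val,y_val Held-out validation subset (never touched during
#'   training).
#' @param protocol An [eval_protocol()].
#' @param seed Integer seed for weight initialization and training noise.
#' @param epochs Epoch budget; defaults to `protocol$eval_epochs`.
#' @return A list with `score`, the trained `model`, and its loss `history`.
#' @export
evaluate_config <- function(config, x_train, y_train, x_val, y_val,
                            protocol, seed = 1L,
                            epochs = protocol$eval_epochs) {
  stopifnot(inherits(config, "network_config"),
            inherits(protocol, "eval_protocol"))
  x_train <- as_feature_matrix(x_train)
  x_val <- as_feature_matrix(x_val)
  out_width <- if (protocol$task == "classification") {
    max(as.integer(y_train), as.integer(y_val))
  } else 1L
  layer_sizes <- c(ncol(x_train), config$hidden_layer_sizes, out_width)
  model <- mlp_model(layer_sizes, task = protocol$task, seed = seed)
  settings <- config_to_settings(
    config, epochs = epochs,
    batch_size = min(protocol$batch_size, nrow(x_train)), seed = seed)
  fit <- sgd_train(model, x_train, y_train, settings)
  if (fit$history$diverged) {
    return(list(score = -Inf, model = fit$model, history = fit$history))
  }
  score <- if (protocol$fitness_metric == "training_loss") {
    -fit$history$final_loss
  } else if (protocol$task == "classification") {
    accuracy(as.integer(y_val), predict(fit$model, x_val)$labels)
  } else {
    -mse(as.numeric(y_val), predict(fit$model, x_val)$values)
  }
  if (!is.finite(score)) score <- -Inf
  list(score = score, model = fit$model, history = fit$history)
}

#' Score a swarm of particle positions
#'
#' Decodes each position and evaluates it with [evaluate_config()].  Each
#' particle gets a deterministic seed derived from the master seed and its
#' index, so batch evaluation equals evaluating each particle singly with
#' the same derived seed, and the output order follows the input order.
#'
#' @param positions A particles x m matrix, or a list of position vectors.
#' @param space A [search_space()].
#' @param x_train,y_train,x_val,y_val The fixed lambda split.
#' @param protocol An [eval_protocol()].
#' @param seed Master seed.
#' @return Numeric vector of scores, one per position (`-Inf` for divergent
#'   candidates).
#' @export
batch_evaluate <- function(positions, space, x_train, y_train, x_val, y_val,
                           protocol, seed = 1L) {
  if (is.list(positions)) positions <- do.call(rbind, positions)
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = 1L)
  vapply(seq_len(nrow(positions)), function(i) {
    config <- decode_particle(positions[i, ], space)
    evaluate_config(config, x_train, y_train, x_val, y_val, protocol,
                    seed = derive_seed(seed, i))$score
  }, numeric(1))
}

#' Swarm search over network configurations
#'
#' End-to-end hyperparameter search on one training set: the data is split
#' once by `protocol$lambda` (the same split scores every generation, so
#' personal-best scores stay comparable), and the swarm maximizes the
#' validation score of briefly-trained networks over the search box.
#'
#' @param features,targets Training data.
#' @param space A [search_space()].
#' @param pso A [pso_settings()].
#' @param protocol An [eval_protocol()].
#' @param seed Master seed for the split and the per-candidate training
#'   seeds (the swarm's own seed lives in `pso`).
#' @return A `pso_result` (see [run_pso()]) with the `space`, `protocol`,
#'   and split indices attached.
#' @export
search_network <- function(features, targets, space, pso = pso_settings(),
                           protocol = eval_protocol(), seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  x <- as_feature_matrix(features)
  split <- split_train_val(targets, protocol$lambda,
                           seed = derive_seed(seed, 0L),
                           task = protocol$task)
  x_train <- x[split$train, , drop = FALSE]
  y_train <- targets[split$train]
  x_val <- x[split$val, , drop = FALSE]
  y_val <- targets[split$val]
  fitness <- function(positions) {
    batch_evaluate(positions, space, x_train, y_train, x_val, y_val,
                   protocol, seed = seed)
  }
  result <- run_pso(fitness, space$lower, space$upper, pso,
                    vectorized = TRUE)
  result$space <- space
  result$protocol <- protocol
  result$split <- split
  result
}
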