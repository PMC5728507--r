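# Bidirectional mapping between a particle's real vector and a network
# configuration.  The particle layout is fixed as
# (learning_rate, dropout_rate, momentum, decay, neurons of hidden layer 1,
#  neurons of hidden layer 2, ...): m = 4 + hidden_layers dimensions.
# Neuron coordinates stay continuous inside the swarm and are only rounded
# at decode time, so the search dynamics remain smooth.

#' Hyperparameter search space
#'
#' Declares the per-hyperparameter bounds that define the swarm's finite
#' search box.  The number of hidden layers is a constant of the space (only
#' layer widths are searched), and all hidden layers share one neuron-count
#' range.  The defaults are the ranges used for the pixel-classification
#' experiments: learning rate [0.01, 0.9], dropout [0.1, 0.9], momentum
#' [0.1, 0.9], decay [1e-5, 1e-4], two hidden layers with 90-150 neurons.
#' A zero-width bound is legal and pins that hyperparameter.
#'
#' @param learning_rate,dropout,momentum,decay Numeric `(lower, upper)`
#'   pairs.
#' @param hidden_layers Positive integer, number of hidden layers.
#' @param neurons `(lower, upper)` pair of neuron counts applied to every
#'   hidden layer; lower bound >= 1.
#' @return An object of class `search_space` with a `lower`/`upper` box of
#'   dimension `4 + hidden_layers`.
#' @export
search_space <- function(learning_rate = c(0.01, 0.9),
                         dropout = c(0.1, 0.9),
                         momentum = c(0.1, 0.9),
                         decay = c(1e-5, 1e-4),
                         hidden_layers = 2L,
                         neurons = c(90, 150)) {
  check_pair <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        x[1] > x[2]) {
      stop(sprintf("'%s' must be a finite (lower, upper) pair", name),
           call. = FALSE)
    }
    x
  }
  learning_rate <- check_pair(learning_rate, "learning_rate")
  dropout <- check_pair(dropout, "dropout")
  momentum <- check_pair(momentum, "momentum")
  decay <- check_pair(decay, "decay")
  neurons <- check_pair(neurons, "neurons")
  if (neurons[1] < 1) stop("'neurons' lower bound must be >= 1",
                           call. = FALSE)
  hidden_layers <- as.integer(hidden_layers)
  if (hidden_layers < 1L) stop("'hidden_layers' must be >= 1", call. = FALSE)

  lower <- c(learning_rate[1], dropout[1], momentum[1], decay[1],
             rep(neurons[1], hidden_layers))
  upper <- c(learning_rate[2], dropout[2], momentum[2], decay[2],
             rep(neurons[2], hidden_layers))
  names(lower) <- names(upper) <-
    c("learning_rate", "dropout_rate", "momentum", "decay",
      paste0("neurons_", seq_len(hidden_layers)))
  structure(
    list(learning_rate = learning_rate, dropout = dropout,
         momentum = momentum, decay = decay, neurons = neurons,
         hidden_layers = hidden_layers,
         m = 4L + hidden_layers, lower = lower, upper = upper),
    class = "search_space"
  )
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("Search space (m = %d):\n", x$m))
  for (nm in c("learning_rate", "dropout", "momentum", "decay", "neurons")) {
    cat(sprintf("  %-13s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  cat(sprintf("  hidden layers: %d\n", x$hidden_layers))
  invisible(x)
}

#' Decode a particle position into a network configuration
#'
#' The first four coordinates map, in fixed order, to learning rate, dropout
#' rate, momentum and decay; the remaining coordinates are rounded half-up
#' to integer neuron counts and clipped to the neuron bounds.
#'
#' @param position Numeric vector of length `space$m`.
#' @param space A [search_space()].
#' @return An object of class `network_config`: `learning_rate`,
#'   `dropout_rate`, `momentum`, `decay`, `hidden_layer_sizes`.
#' @examples
#' sp <- search_space()
#' decode_particle(c(0.01, 0.1, 0.1, 1e-5, 120.7, 99.2), sp)
#' @export
decode_particle <- function(position, space) {
  stopifnot(inherits(space, "search_space"))
  position <- as.numeric(position)
  if (length(position) != space$m) {
    stop(sprintf("position has %d dimensions but the space needs %d",
                 length(position), space$m), call. = FALSE)
  }
  sizes <- round_half_up(position[-(1:4)])
  sizes <- pmin(pmax(sizes, ceiling(space$neurons[1])),
                floor(space$neurons[2]))
  structure(
    list(learning_rate = position[1], dropout_rate = position[2],
         momentum = position[3], decay = position[4],
         hidden_layer_sizes = as.integer(sizes)),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "Network config: lr %.5g, dropout %.3g, momentum %.3g, decay %.3g, hidden [%s]\n",
    x$learning_rate, x$dropout_rate, x$momentum, x$decay,
    paste(x$hidden_layer_sizes, collapse = ", ")))
  invisible(x)
}

#' Encode a network configuration as a particle position
#'
#' Exact inverse of [decode_particle()] on in-bounds configurations: integer
#' neuron counts are placed unchanged in the tail coordinates.
#'
#' @param config A `network_config`.
#' @param space A [search_space()].
#' @return Numeric vector of length `space$m`.
#' @export
encode_config <- function(config, space) {
  stopifnot(inherits(config, "network_config"),
            inherits(space, "search_space"))
  check_in <- function(value, bounds, name) {
    if (any(value < bounds[1] - 1e-12) || any(value > bounds[2] + 1e-12)) {
      stop(sprintf("'%s' (%s) lies outside its bounds [%g, %g]",
                   name, paste(signif(value, 6), collapse = ", "),
                   bounds[1], bounds[2]), call. = FALSE)
    }
  }
  check_in(config$learning_rate, space$learning_rate, "learning_rate")
  check_in(config$dropout_rate, space$dropout, "dropout_rate")
  check_in(config$momentum, space$momentum, "momentum")
  check_in(config$decay, space$decay, "decay")
  check_in(config$hidden_layer_sizes, space$neurons, "hidden_layer_sizes")
  if (length(config$hidden_layer_sizes) != space$hidden_layers) {
    stop(sprintf("config has %d hidden layers but the space fixes %d",
                 length(config$hidden_layer_sizes), space$hidden_layers),
         call. = FALSE)
  }
  c(config$learning_rate, config$dropout_rate, config$momentum,
    config$decay, as.numeric(config$hidden_layer_sizes))
}

#' Draw a random network configuration
#'
#' Each hyperparameter is uniform over its bounds and each layer width is a
#' uniform integer over the neuron range — the random baseline's generator.
#'
#' @param space A [search_space()].
#' @param seed Integer seed.
#' @return A `network_config`.
#' @export
random_config <- function(space, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  with_seed(seed, {
    lo <- ceiling(space$neurons[1])
    hi <- floor(space$neurons[2])
    structure(
      list(
        learning_rate = stats::runif(1, space$learning_rate[1],
                                     space$learning_rate[2]),
        dropout_rate = stats::runif(1, space$dropout[1], space$dropout[2]),
        momentum = stats::runif(1, space$momentum[1], space$momentum[2]),
        decay = stats::runif(1, space$decay[1], space$decay[2]),
        hidden_layer_sizes =
          as.integer(sample(lo:hi, space$hidden_layers, replace = TRUE))
      ),
      class = "network_config"
    )
  })
}

#' Convert a network configuration into trainer settings
#'
#' @param config A `network_config`.
#' @param epochs,batch_size,seed Training-loop parameters not searched by
#'   the swarm.
#' @return A [train_settings()] object.
#' @export
config_to_settings <- function(config, epochs, batch_size, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  train_settings(learning_rate = config$learning_rate,
                 momentum = config$momentum,
                 decay = config$decay,
                 dropout_rate = config$dropout_rate,
                 epochs = epochs, batch_size = batch_size, seed = seed)
}

#' Serialize / deserialize a search space
#'
#' Written alongside search results so that any particle vector recorded in
#' a trace stays decodable later.
#'
#' @param space A [search_space()].
#' @param path File path.
#' @return `path` invisibly (write); a `search_space` (read).
#' @export
write_search_space <- function(space, path) {
  stopifnot(inherits(space, "search_space"))
  jsonlite::write_json(
    list(learning_rate = space$learning_rate, dropout = space$dropout,
         momentum = space$momentum, decay = space$decay,
         neurons = space$neurons, hidden_layers = space$hidden_layers),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_search_space
#' @export
read_search_space <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  search_space(learning_rate = s$learning_rate, dropout = s$dropout,
               momentum = s$momentum, decay = s$decay,
               hidden_layers = s$hidden_layers, neurons = s$neurons)
}
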