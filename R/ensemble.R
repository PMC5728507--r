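# Final-model construction: retrain one network per personal-best solution
# on the full training data, keep the top h by validation score, and fuse
# classification predictions by majority vote (regression by averaging).

new_scored_classifier <- function(model, config, score, history = NULL) {
  structure(list(model = model, config = config, score = score,
                 history = history),
            class = "scored_classifier")
}

#' Retrain final candidate models from swarm solutions
#'
#' Each solution (typically the swarm's personal-best positions, optionally
#' with the global best appended) is decoded and a fresh network is trained
#' for `protocol$final_epochs` on all training samples.  For ranking, each
#' finished model is scored on a held-out validation split of the same
#' training data (re-using `protocol$lambda`); candidates whose training
#' diverges are retained with score `-Inf` so they are never selected.
#'
#' @param solutions List of particle position vectors (or a matrix with one
#'   position per row).
#' @param space A [search_space()].
#' @param features,targets The full training data.
#' @param protocol An [eval_protocol()].
#' @param seed Master seed; candidate i trains with a seed derived from it.
#' @return A list of `scored_classifier` objects, one per solution, in
#'   input order.
#' @export
train_final <- function(solutions, space, features, targets,
                        protocol = eval_protocol(), seed = 1L) {
  stopifnot(inherits(space, "search_space"),
            inherits(protocol, "eval_protocol"))
  if (is.matrix(solutions)) {
    solutions <- lapply(seq_len(nrow(solutions)),
                        function(i) solutions[i, ])
  }
  x <- as_feature_matrix(features)
  split <- split_train_val(targets, protocol$lambda,
                           seed = derive_seed(seed, 0L),
                           task = protocol$task)
  x_val <- x[split$val, , drop = FALSE]
  y_val <- targets[split$val]
  out_width <- if (protocol$task == "classification") {
    max(as.integer(targets))
  } else 1L

  lapply(seq_along(solutions), function(i) {
    config <- decode_particle(solutions[[i]], space)
    cand_seed <- derive_seed(seed, i)
    model <- mlp_model(c(ncol(x), config$hidden_layer_sizes, out_width),
                       task = protocol$task, seed = cand_seed)
    settings <- config_to_settings(
      config, epochs = protocol$final_epochs,
      batch_size = min(protocol$batch_size, nrow(x)), seed = cand_seed)
    fit <- sgd_train(model, x, targets, settings)
    score <- if (fit$history$diverged) {
      -Inf
    } else if (protocol$task == "classification") {
      accuracy(as.integer(y_val), predict(fit$model, x_val)$labels)
    } else {
      -mse(as.numeric(y_val), predict(fit$model, x_val)$values)
    }
    if (!is.finite(score) && !fit$history$diverged) score <- -Inf
    new_scored_classifier(fit$model, config, score, fit$history)
  })
}

#' Select the top-scoring candidates into an ensemble
#'
#' Keeps the `h` highest-scored candidates without any retraining; ties are
#' broken in favor of the lower candidate index.
#'
#' @param candidates List of `scored_classifier` objects.
#' @param h Ensemble size, `1 <= h <= length(candidates)`.
#' @return An object of class `nn_ensemble` with `members` (the selected
#'   candidates, best first), `member_index` (their positions in the
#'   candidate pool), `h`, and `task`.
#' @export
select_top <- function(candidates, h) {
  if (!length(candidates) ||
      !all(vapply(candidates, inherits, logical(1), "scored_classifier"))) {
    stop("'candidates' must be a non-empty list of scored classifiers",
         call. = FALSE)
  }
  h <- as.integer(h)
  if (h < 1L || h > length(candidates)) {
    stop(sprintf("'h' must lie in 1..%d", length(candidates)), call. = FALSE)
  }
  scores <- vapply(candidates, function(c) c$score, numeric(1))
  picked <- order(-scores, seq_along(scores))[seq_len(h)]
  structure(
    list(members = candidates[picked], member_index = picked, h = h,
         task = candidates[[picked[1L]]]$model$task),
    class = "nn_ensemble"
  )
}

#' @export
print.nn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d %s members; scores %s\n", x$h, x$task,
              paste(signif(vapply(x$members, function(m) m$score,
                                  numeric(1)), 4), collapse = ", ")))
  invisible(x)
}

#' Majority-vote ensemble prediction
#'
#' Each member votes for its argmax class; the modal label wins.  A tie in
#' vote counts is broken by the larger sum of the members' class scores,
#' then by the lower class index.
#'
#' @param ensemble An `nn_ensemble` over classification members.
#' @param features Numeric feature matrix.
#' @return Integer vector of 1-based predicted labels.
#' @export
vote_predict <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  if (!length(ensemble$members)) stop("empty ensemble", call. = FALSE)
  if (ensemble$task != "classification") {
    stop("vote_predict requires a classification ensemble; see mean_predict",
         call. = FALSE)
  }
  preds <- lapply(ensemble$members,
                  function(m) predict(m$model, features))
  n <- length(preds[[1L]]$labels)
  n_classes <- ncol(preds[[1L]]$scores)
  votes <- vapply(preds, function(p) p$labels, integer(n))
  if (n == 1L) votes <- matrix(votes, nrow = 1L)
  score_sum <- Reduce(`+`, lapply(preds, function(p) p$scores))
  vapply(seq_len(n), function(i) {
    counts <- tabulate(votes[i, ], nbins = n_classes)
    tied <- which(counts == max(counts))
    if (length(tied) == 1L) return(tied)
    tied[which.max(score_sum[i, tied])]   # which.max keeps the lower index on ties
  }, integer(1))
}

#' Averaged ensemble prediction for regression
#'
#' The default fusion is the unweighted mean of the members' scalar
#' outputs; `weights = "score"` weights members by their (shifted) ranking
#' scores instead.
#'
#' @param ensemble An `nn_ensemble` over regression members.
#' @param features Numeric feature matrix.
#' @param weights `"uniform"` (default) or `"score"`.
#' @return Numeric vector of fused predictions.
#' @export
mean_predict <- function(ensemble, features,
                         weights = c("uniform", "score")) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  weights <- match.arg(weights)
  if (!length(ensemble$members)) stop("empty ensemble", call. = FALSE)
  if (ensemble$task != "regression") {
    stop("mean_predict requires a regression ensemble; see vote_predict",
         call. = FALSE)
  }
  outputs <- vapply(ensemble$members,
                    function(m) predict(m$model, features)$values,
                    numeric(nrow(as_feature_matrix(features))))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1L)
  if (weights == "uniform") {
    rowMeans(outputs)
  } else {
    s <- vapply(ensemble$members, function(m) m$score, numeric(1))
    w <- s - min(s)
    if (sum(w) == 0) w <- rep(1, length(s))
    as.numeric(outputs %*% (w / sum(w)))
  }
}

#' Write an ensemble manifest with its member model archives
#'
#' Saves every member with [write_mlp()] under `dir` and writes
#' `manifest.json` listing, per member, its configuration, ranking score,
#' and model archive path — enough to reload the ensemble for
#' prediction-only runs with [read_ensemble()].
#'
#' @param ensemble An `nn_ensemble`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(ensemble$members), function(i) {
    m <- ensemble$members[[i]]
    file <- sprintf("member_%02d.json", i)
    write_mlp(m$model, file.path(dir, file))
    list(file = file, score = m$score, config = unclass(m$config))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(format = "pswarmnet-ensemble", h = ensemble$h,
         task = ensemble$task, members = entries),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "pswarmnet-ensemble")) {
    stop("not a pswarmnet ensemble manifest", call. = FALSE)
  }
  members <- lapply(manifest$members, function(e) {
    model <- read_mlp(file.path(dir, e$file))$model
    config <- structure(
      list(learning_rate = e$config$learning_rate,
           dropout_rate = e$config$dropout_rate,
           momentum = e$config$momentum, decay = e$config$decay,
           hidden_layer_sizes = as.integer(unlist(e$config$hidden_layer_sizes))),
      class = "network_config")
    new_scored_classifier(model, config, as.numeric(e$score))
  })
  structure(
    list(members = members, member_index = seq_along(members),
         h = length(members), task = manifest$task),
    class = "nn_ensemble"
  )
}
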