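# Experiment orchestration: k-fold cross-validation, metrics, and the
# comparison of swarm-selected configurations against an equal-budget
# random baseline, reported as candidate-score tables with Avg/Std rows.

#' Stratified k-fold split
#'
#' Partitions `1..n` into k disjoint, exhaustive folds of near-equal size;
#' fold i's test set is fold i and its training set is the rest.
#' Classification folds are stratified: within each class the first
#' `n_c %% k` folds receive one extra record, so global fold sizes also
#' follow the first-folds-get-the-remainder rule.
#'
#' @param targets Label or target vector; its length defines n, its values
#'   stratify classification folds.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @param task `"classification"` (stratified) or `"regression"`.
#' @return A list of k lists, each with integer index vectors `train` and
#'   `test`.
#' @export
kfold_split <- function(targets, k, seed = 1L,
                        task = c("classification", "regression")) {
  task <- match.arg(task)
  n <- length(targets)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (k > n) stop("'k' exceeds the number of records", call. = FALSE)

  chunk <- function(idx) {
    # sizes: first (length %% k) folds get one extra record
    m <- length(idx)
    sizes <- rep(m %/% k, k) + (seq_len(k) <= m %% k)
    split(idx, rep(seq_len(k), sizes))
  }
  with_seed(seed, {
    fold_members <- if (task == "regression") {
      chunk(sample.int(n))
    } else {
      per_class <- lapply(split(seq_len(n), targets),
                          function(idx) chunk(sample(idx)))
      lapply(seq_len(k), function(f) {
        sort(unlist(lapply(per_class, `[[`, f), use.names = FALSE))
      })
    }
    lapply(seq_len(k), function(f) {
      test <- sort(fold_members[[f]])
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

#' Mean absolute percentage error
#'
#' `mean(|actual - predicted| / |actual|)`.  Zero actual values are refused
#' unless an `epsilon` floor for the denominator is supplied.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @param epsilon Optional positive floor applied to `|actual|` in the
#'   denominator for near-zero targets.
#' @return A non-negative scalar (1.0 means 100% error on average).
#' @examples
#' mape(c(2, 4), c(1, 2))   # 0.5
#' @export
mape <- function(actual, predicted, epsilon = NULL) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  if (length(actual) != length(predicted) || !length(actual)) {
    stop("'actual' and 'predicted' must be non-empty and equally long",
         call. = FALSE)
  }
  denom <- abs(actual)
  if (is.null(epsilon)) {
    if (any(denom == 0)) {
      stop("zero 'actual' values: supply an 'epsilon' denominator floor",
           call. = FALSE)
    }
  } else {
    stopifnot_scalar_number(epsilon, "epsilon")
    if (epsilon <= 0) stop("'epsilon' must be positive", call. = FALSE)
    denom <- pmax(denom, epsilon)
  }
  mean(abs(actual - predicted) / denom)
}

#' Classification accuracy
#'
#' @param true_labels,predicted_labels Equal-length vectors.
#' @return Fraction of exact matches in [0, 1].
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must be equally long", call. = FALSE)
  }
  if (!length(true_labels)) stop("empty label vectors", call. = FALSE)
  mean(true_labels == predicted_labels)
}

resolve_dataset <- function(data_spec) {
  if (inherits(data_spec, "nn_dataset")) return(data_spec)
  if (!is.list(data_spec) || is.null(data_spec$type)) {
    stop("'data' must be an nn_dataset or a generator/file spec list",
         call. = FALSE)
  }
  # YAML 1.1 reads a bare `n:` key as a boolean, so config files use
  # n_samples/n_features; the short names still work from R lists
  n <- data_spec$n_samples %||% data_spec$n
  d <- data_spec$n_features %||% data_spec$d
  switch(data_spec$type,
    classification = make_classification_data(
      n = n, d = d, n_classes = data_spec$n_classes,
      separation = data_spec$separation %||% 4,
      seed = data_spec$seed %||% 1L),
    qsar = make_qsar_data(
      n_molecules = n, n_descriptors = d,
      latent_rank = data_spec$latent_rank %||% 10L,
      noise_sd = data_spec$noise_sd %||% 0.1,
      seed = data_spec$seed %||% 1L),
    csv = read_dataset_csv(data_spec$path,
                           label_col = data_spec$label_col %||% "label",
                           task = data_spec$task %||% "classification"),
    stop(sprintf("unknown data type '%s'", data_spec$type), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_comparison_config <- function(config) {
  required <- c("data", "space", "pso", "protocol")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop(sprintf("comparison config is missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

test_metric <- function(model_or_labels, y_test, task) {
  if (task == "classification") accuracy(as.integer(y_test), model_or_labels)
  else mape(as.numeric(y_test), model_or_labels)
}

# Score one trained candidate on the test fold.  Classification reports
# accuracy (higher better); regression reports MAPE (lower better), matching
# how the two tasks are tabulated.
candidate_test_score <- function(candidate, x_test, y_test, task) {
  if (!is.finite(candidate$score)) return(NA_real_)
  p <- predict(candidate$model, x_test)
  if (task == "classification") test_metric(p$labels, y_test, task)
  else test_metric(p$values, y_test, task)
}

run_one_arm <- function(arm, x, y, train_idx, test_idx, space, pso_set,
                        protocol, h, fold_seed) {
  x_train <- x[train_idx, , drop = FALSE]
  y_train <- y[train_idx]
  x_test <- x[test_idx, , drop = FALSE]
  y_test <- y[test_idx]
  task <- protocol$task

  if (arm == "pso") {
    search <- search_network(
      x_train, y_train, space,
      pso = pso_set, protocol = protocol, seed = fold_seed)
    solutions <- search$pbest_positions
    individual_solution <- search$gbest_position
    trace <- search$trace
  } else {
    solutions <- lapply(seq_len(pso_set$population_size), function(i) {
      encode_config(random_config(space, seed = derive_seed(fold_seed, 100L + i)),
                    space)
    })
    individual_solution <- NULL
    trace <- NULL
  }

  candidates <- train_final(solutions, space, x_train, y_train,
                            protocol, seed = derive_seed(fold_seed, 1L))
  cand_scores <- vapply(candidates, candidate_test_score, numeric(1),
                        x_test = x_test, y_test = y_test, task = task)

  ensemble <- select_top(candidates, min(h, length(candidates)))
  ens_score <- if (task == "classification") {
    test_metric(vote_predict(ensemble, x_test), y_test, task)
  } else {
    test_metric(mean_predict(ensemble, x_test), y_test, task)
  }

  individual <- if (is.null(individual_solution)) {
    # random arm: best-ranked candidate stands in for the swarm's gbest
    candidates[[select_top(candidates, 1L)$member_index]]
  } else {
    train_final(list(individual_solution), space, x_train, y_train,
                protocol, seed = derive_seed(fold_seed, 2L))[[1L]]
  }
  ind_score <- candidate_test_score(individual, x_test, y_test, task)

  list(candidate_scores = cand_scores, ensemble_score = ens_score,
       individual_score = ind_score, trace = trace,
       validation_scores = vapply(candidates, function(c) c$score,
                                  numeric(1)))
}

#' Run the full swarm-vs-random comparison experiment
#'
#' For each cross-validation fold, both arms are run on the fold's training
#' data and scored on its test data.  The swarm arm searches with
#' [search_network()] and retrains its personal-best solutions as final
#' candidates (plus the global best as the "individual" model); the random
#' arm draws the same number of candidate configurations uniformly from the
#' same space and trains them with the same final epoch budget, so both
#' arms field equally many, equally trained candidate networks.  Top-h
#' candidates of each arm are fused into an ensemble.
#'
#' @param config A named list (or path to a YAML/JSON file) with keys:
#'   `data` (an `nn_dataset` or a generator spec list with `type`
#'   `"classification"`, `"qsar"` or `"csv"`), `space` (a [search_space()]
#'   or its argument list), `pso` (a [pso_settings()] or argument list),
#'   `protocol` (an [eval_protocol()] or argument list), and optionally
#'   `k` (folds, default 5), `h` (ensemble size, default the population
#'   size), `mode` (`"kfold"` or `"holdout"`), `holdout_fraction` (default
#'   0.8), and `seed` (default 1).
#' @return An object of class `experiment_report`: `candidate_table` (one
#'   row per candidate plus Avg/Std rows, one column per arm and fold),
#'   `ensemble_individual` (per-fold ensemble and individual scores for
#'   both arms), `traces` (per-fold swarm traces), and `metadata` (seeds,
#'   config hash, timings).  Classification cells are accuracies; regression
#'   cells are MAPEs.
#' @export
run_comparison <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  validate_comparison_config(config)
  dataset <- resolve_dataset(config$data)
  space <- if (inherits(config$space, "search_space")) config$space
           else do.call(search_space, config$space)
  pso_set <- if (inherits(config$pso, "pso_settings")) config$pso
             else do.call(pso_settings, config$pso)
  protocol <- if (inherits(config$protocol, "eval_protocol")) {
    config$protocol
  } else {
    args <- config$protocol
    args$task <- args$task %||% dataset$task
    do.call(eval_protocol, args)
  }
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$mode %||% "kfold"
  h <- as.integer(config$h %||% pso_set$population_size)
  task <- dataset$task
  x <- dataset$features
  y <- dataset$targets

  folds <- if (mode == "holdout") {
    frac <- config$holdout_fraction %||% 0.8
    s <- split_train_val(y, frac, seed = seed, task = task)
    list(list(train = s$train, test = s$val))
  } else {
    kfold_split(y, as.integer(config$k %||% 5L), seed = seed, task = task)
  }

  t0 <- proc.time()[["elapsed"]]
  arms <- c("pso", "random")
  fold_results <- lapply(seq_along(folds), function(f) {
    fold_seed <- derive_seed(seed, f)
    lapply(stats::setNames(arms, arms), function(arm) {
      run_one_arm(arm, x, y, folds[[f]]$train, folds[[f]]$test,
                  space, pso_set, protocol, h, fold_seed)
    })
  })
  elapsed <- proc.time()[["elapsed"]] - t0

  pop <- pso_set$population_size
  cols <- list()
  for (arm in arms) {
    for (f in seq_along(folds)) {
      cols[[sprintf("%s_fold%d", arm, f)]] <-
        fold_results[[f]][[arm]]$candidate_scores
    }
  }
  body <- as.data.frame(cols)
  summary_rows <- rbind(Avg = colMeans(body, na.rm = TRUE),
                        Std = apply(body, 2L, stats::sd, na.rm = TRUE))
  candidate_table <- rbind(body, as.data.frame(summary_rows))
  rownames(candidate_table) <- c(seq_len(pop), "Avg", "Std")

  ensemble_individual <- do.call(rbind, lapply(seq_along(folds), function(f) {
    do.call(rbind, lapply(arms, function(arm) {
      r <- fold_results[[f]][[arm]]
      data.frame(fold = f, arm = arm, ensemble = r$ensemble_score,
                 individual = r$individual_score,
                 mean_validation = mean(r$validation_scores[
                   is.finite(r$validation_scores)]))
    }))
  }))

  structure(
    list(candidate_table = candidate_table,
         ensemble_individual = ensemble_individual,
         traces = lapply(fold_results, function(r) r$pso$trace),
         metadata = list(
           seed = seed, task = task, mode = mode, h = h,
           n = nrow(x), d = ncol(x), k = length(folds),
           population_size = pop,
           config_hash = hash_config(list(
             space = unclass(space), pso = unclass(pso_set),
             protocol = unclass(protocol), seed = seed, mode = mode, h = h)),
           elapsed_seconds = elapsed)),
    class = "experiment_report"
  )
}

# Stable content hash of a config (md5 of its canonical deparse), embedded
# in every report for provenance.
hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.experiment_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Comparison experiment (%s, %s): n = %d, %d folds, %d candidates/arm\n",
    md$task, md$mode, md$n, md$k, md$population_size))
  metric <- if (md$task == "classification") "accuracy" else "MAPE"
  cat(sprintf("Candidate %s (Avg row):\n", metric))
  print(round(x$candidate_table["Avg", ], 4))
  cat("Ensemble / individual per fold:\n")
  print(x$ensemble_individual, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits `candidates.csv` (the per-candidate table with Avg/Std rows),
#' `ensemble_individual.csv`, per-fold `trace_fold<k>.csv` swarm traces,
#' and `summary.json` with the metadata — the report bodies are a pure
#' function of config + seed (timings live only in the JSON summary).
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$candidate_table,
                   file.path(dir, "candidates.csv"))
  utils::write.csv(report$ensemble_individual,
                   file.path(dir, "ensemble_individual.csv"),
                   row.names = FALSE)
  for (f in seq_along(report$traces)) {
    if (!is.null(report$traces[[f]])) {
      utils::write.csv(report$traces[[f]],
                       file.path(dir, sprintf("trace_fold%d.csv", f)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report$metadata,
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list as accepted by [run_comparison()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
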