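test_that("k-fold splits are disjoint, exhaustive, and near-equal", {
  y <- rep(1:2, 50)
  folds <- kfold_split(y, 5, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), 1:100)
  expect_equal(sum(lengths(tests)), 100)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:100)
  }

  # uneven n: the first n %% k folds get one extra record
  folds <- kfold_split(rnorm(103), 5, seed = 2, task = "regression")
  expect_equal(lengths(lapply(folds, `[[`, "test")),
               c(21L, 21L, 21L, 20L, 20L))

  expect_error(kfold_split(1:3, 5), "exceeds")
  expect_error(kfold_split(1:10, 1), ">= 2")
})

test_that("stratified folds preserve class proportions", {
  y <- rep(1:4, each = 50)
  folds <- kfold_split(y, 5, seed = 3)
  for (f in folds) {
    props <- table(y[f$test]) / length(f$test)
    expect_true(all(abs(props - 0.25) <= 0.02))
  }
})

test_that("mape follows the absolute-percentage definition", {
  expect_equal(mape(c(3, 7), c(3, 7)), 0)
  expect_equal(mape(1, 2), 1.0)
  expect_equal(mape(c(2, 4), c(1, 2)), 0.5)
  expect_error(mape(c(0, 1), c(1, 1)), "epsilon")
  expect_equal(mape(c(0, 1), c(1, 1), epsilon = 0.5), mean(c(2, 0)))
  expect_error(mape(1:3, 1:2), "equally long")
})

test_that("accuracy counts exact matches", {
  expect_equal(accuracy(1:4, 1:4), 1.0)
  expect_equal(accuracy(1:4, 5:8), 0.0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 9)), 0.75)
  expect_error(accuracy(1:3, 1:4), "equally long")
})

desk_comparison_config <- function(seed = 1) {
  list(
    data = make_classification_data(120, 8, 2, separation = 3, seed = 11),
    space = desk_space(),
    pso = pso_settings(population_size = 4, max_iterations = 2,
                       seed = seed),
    protocol = eval_protocol(eval_epochs = 2, final_epochs = 3,
                             batch_size = 32, task = "classification"),
    k = 2, h = 3, seed = seed
  )
}

test_that("run_comparison reports both arms with recomputable summaries", {
  report <- run_comparison(desk_comparison_config())
  tab <- report$candidate_table
  # one column per arm per fold, population_size candidate rows + Avg/Std
  expect_equal(ncol(tab), 4)
  expect_equal(nrow(tab), 4 + 2)
  body <- tab[1:4, ]
  expect_equal(unlist(tab["Avg", ]), colMeans(body, na.rm = TRUE),
               ignore_attr = TRUE)
  expect_equal(unlist(tab["Std", ]),
               apply(body, 2, sd, na.rm = TRUE), ignore_attr = TRUE)
  expect_true(all(body >= 0 & body <= 1, na.rm = TRUE))

  ei <- report$ensemble_individual
  expect_equal(nrow(ei), 4)  # 2 folds x 2 arms
  expect_setequal(ei$arm, c("pso", "random"))
  expect_true(all(ei$ensemble >= 0 & ei$ensemble <= 1))

  expect_false(is.null(report$metadata$config_hash))
})

test_that("reports are a pure function of config + seed", {
  a <- run_comparison(desk_comparison_config(seed = 4))
  b <- run_comparison(desk_comparison_config(seed = 4))
  expect_identical(a$candidate_table, b$candidate_table)
  expect_identical(a$ensemble_individual, b$ensemble_individual)
  expect_identical(a$metadata$config_hash, b$metadata$config_hash)

  dir <- tempfile()
  write_report(a, dir)
  expect_true(file.exists(file.path(dir, "candidates.csv")))
  expect_true(file.exists(file.path(dir, "ensemble_individual.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
})

test_that("invalid configs fail with the offending keys", {
  expect_error(run_comparison(list(data = list(type = "classification"))),
               "space.*pso.*protocol")
})

test_that("holdout mode runs a single 80/20 split", {
  config <- desk_comparison_config()
  config$mode <- "holdout"
  config$holdout_fraction <- 0.8
  config$k <- NULL
  report <- run_comparison(config)
  expect_equal(report$metadata$k, 1L)
  expect_equal(ncol(report$candidate_table), 2)
})

test_that("config files round-trip through YAML", {
  cfg <- list(data = list(type = "classification", n_samples = 120,
                          n_features = 8, n_classes = 2, seed = 1),
              space = list(hidden_layers = 2, neurons = c(4, 16)),
              pso = list(population_size = 4, max_iterations = 2),
              protocol = list(eval_epochs = 2, final_epochs = 3,
                              batch_size = 32),
              k = 2, seed = 1)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$pso$population_size, 4)
  expect_equal(back$space$neurons, c(4, 16))
})

test_that("the command-line interface script parses", {
  cli <- system.file("cli", "pswarmnet.R", package = "pswarmnet")
  if (cli == "") cli <- file.path("..", "..", "inst", "cli", "pswarmnet.R")
  expect_silent(parse(cli))
})
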