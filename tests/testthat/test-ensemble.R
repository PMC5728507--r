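test_that("train_final returns one ranked candidate per solution", {
  d <- separable_fixture(120, 5)
  sp <- desk_space()
  protocol <- eval_protocol(eval_epochs = 2, final_epochs = 4,
                            batch_size = 32, task = "classification")
  solutions <- lapply(1:3, function(i) {
    pswarmnet:::with_seed(i, runif(sp$m, sp$lower, sp$upper))
  })
  candidates <- train_final(solutions, sp, d$features, d$targets,
                            protocol, seed = 1)
  expect_length(candidates, 3)
  for (c in candidates) {
    expect_s3_class(c, "scored_classifier")
    expect_true(is.finite(c$score))
    expect_identical(c$model$layer_sizes[-c(1, 4)],
                     c$config$hidden_layer_sizes)
  }
})

test_that("select_top keeps the h best with index tie-breaking", {
  pool <- list(constant_vote_classifier(2, c(1, 0), score = 0.90),
               constant_vote_classifier(2, c(0, 1), score = 0.80),
               constant_vote_classifier(2, c(1, 0), score = 0.95))
  top2 <- select_top(pool, 2)
  expect_equal(vapply(top2$members, function(m) m$score, numeric(1)),
               c(0.95, 0.90))
  expect_equal(top2$member_index, c(3L, 1L))

  expect_length(select_top(pool, 3)$members, 3)

  tie <- list(constant_vote_classifier(2, c(1, 0), score = 0.9),
              constant_vote_classifier(2, c(0, 1), score = 0.9),
              constant_vote_classifier(2, c(1, 0), score = 0.8))
  expect_equal(select_top(tie, 1)$member_index, 1L)

  expect_error(select_top(pool, 0), "1..3")
  expect_error(select_top(pool, 4), "1..3")

  # selecting everything from an ensemble of size h is idempotent
  again <- select_top(select_top(pool, 2)$members, 2)
  expect_equal(vapply(again$members, function(m) m$score, numeric(1)),
               c(0.95, 0.90))
})

test_that("majority vote follows the modal label with score tie-breaks", {
  x <- matrix(runif(6), 3, 2)
  # members voting 1, 1, 2 -> majority 1
  ens <- select_top(list(constant_vote_classifier(2, c(2, 0, 0)),
                         constant_vote_classifier(2, c(2, 0, 0)),
                         constant_vote_classifier(2, c(0, 2, 0))), 3)
  expect_equal(vote_predict(ens, x), rep(1L, 3))

  # unanimity wins for any h
  for (h in 1:3) {
    u <- select_top(rep(list(constant_vote_classifier(2, c(0, 2, 0))), 3), h)
    expect_equal(vote_predict(u, x), rep(2L, 3))
  }

  # a 1-1 vote falls back to the larger summed class score
  tie <- select_top(list(constant_vote_classifier(2, c(1.2, 0.1)),
                         constant_vote_classifier(2, c(0.2, 0.9))), 2)
  score_sum <- predict(tie$members[[1]]$model, x)$scores +
    predict(tie$members[[2]]$model, x)$scores
  expect_true(all(score_sum[, 1] > score_sum[, 2]))
  expect_equal(vote_predict(tie, x), rep(1L, 3))
})

test_that("an h = 1 ensemble predicts exactly like its single member", {
  d <- separable_fixture(100, 5)
  sp <- desk_space()
  protocol <- eval_protocol(eval_epochs = 2, final_epochs = 4,
                            batch_size = 32, task = "classification")
  candidates <- train_final(
    list(pswarmnet:::with_seed(1, runif(sp$m, sp$lower, sp$upper))),
    sp, d$features, d$targets, protocol, seed = 2)
  solo <- select_top(candidates, 1)
  expect_identical(vote_predict(solo, d$features),
                   predict(solo$members[[1]]$model, d$features)$labels)
})

test_that("regression fusion averages member outputs", {
  x <- matrix(runif(8), 4, 2)
  ens <- select_top(list(constant_value_regressor(2, 1.0),
                         constant_value_regressor(2, 3.0)), 2)
  expect_equal(mean_predict(ens, x), rep(2.0, 4))

  same <- select_top(rep(list(constant_value_regressor(2, 1.7)), 3), 3)
  expect_equal(mean_predict(same, x), rep(1.7, 4))

  # convexity: the mean prediction's squared error never exceeds the
  # worst member's squared error on any sample
  set.seed(8)
  members <- lapply(rnorm(5, sd = 2), constant_value_regressor, d = 2)
  ens <- select_top(members, 5)
  truth <- rnorm(4)
  fused_err <- (mean_predict(ens, x) - truth)^2
  member_err <- sapply(members,
                       function(m) (predict(m$model, x)$values - truth)^2)
  expect_true(all(fused_err <= apply(member_err, 1, max) + 1e-12))
})

test_that("task-mismatched fusion calls fail loudly", {
  cls <- select_top(list(constant_vote_classifier(2, c(1, 0))), 1)
  reg <- select_top(list(constant_value_regressor(2, 1)), 1)
  expect_error(mean_predict(cls, matrix(0, 1, 2)), "regression")
  expect_error(vote_predict(reg, matrix(0, 1, 2)), "classification")
})

test_that("ensemble manifests reload for prediction-only runs", {
  d <- separable_fixture(100, 5)
  sp <- desk_space()
  protocol <- eval_protocol(eval_epochs = 2, final_epochs = 4,
                            batch_size = 32, task = "classification")
  solutions <- lapply(1:3, function(i) {
    pswarmnet:::with_seed(i, runif(sp$m, sp$lower, sp$upper))
  })
  ens <- select_top(train_final(solutions, sp, d$features, d$targets,
                                protocol, seed = 3), 2)
  dir <- tempfile()
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  expect_identical(vote_predict(back, d$features),
                   vote_predict(ens, d$features))
})
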