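toy <- toy_map_set(n_per_class = 25, offset = 2, seed = 9)
toy_tr <- 1:34; toy_va <- 35:42; toy_te <- 43:50

test_that("training is deterministic given seed, data and config", {
  spec <- build_base_network(21, 10)
  cfg <- train_config(max_iterations = 30, seed = 4)
  f1 <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                      toy$X[, , toy_va], toy$labels[toy_va], cfg)
  f2 <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                      toy$X[, , toy_va], toy$labels[toy_va], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training converges on separable maps with one update per iteration", {
  spec <- build_base_network(21, 10)
  fit <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                       toy$X[, , toy_va], toy$labels[toy_va],
                       train_config(max_iterations = 300, seed = 4))
  h <- fit$history
  expect_true(all(is.finite(h$loss)))
  expect_lt(h$loss[nrow(h)], 0.05)
  expect_equal(h$train_accuracy[nrow(h)], 1)
  # accuracy reaches 1 and stays stable over the final stretch
  expect_true(all(tail(h$train_accuracy, 50) == 1))
  expect_equal(fit$n_updates, 300L)
  # model selection: returned params achieve max validation accuracy
  expect_equal(evaluate(fit, toy$X[, , toy_va], toy$labels[toy_va]),
               max(h$val_accuracy))
  first_best <- min(which(h$val_accuracy == max(h$val_accuracy)))
  expect_equal(fit$best_iteration, first_best)
})

test_that("both optimizers reduce the training loss", {
  spec <- build_base_network(21, 10)
  for (opt in c("adam", "adadelta")) {
    fit <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                         toy$X[, , toy_va], toy$labels[toy_va],
                         train_config(optimizer = opt, max_iterations = 150,
                                      seed = 4))
    expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
    expect_gt(tail(fit$history$train_accuracy, 1), 0.8)
  }
})

test_that("shuffled labels give chance-level validation accuracy", {
  spec <- build_base_network(21, 10)
  set.seed(13)
  ysh <- sample(toy$labels)
  fit <- train_network(spec, toy$X[, , toy_tr], ysh[toy_tr],
                       toy$X[, , toy_va], ysh[toy_va],
                       train_config(max_iterations = 150, seed = 4))
  acc <- evaluate(fit, toy$X[, , toy_te], ysh[toy_te])
  expect_gte(acc, 0.125)  # 0.5 within binomial noise on 8 samples
  expect_lte(acc, 0.875)
})

test_that("empty or single-class partitions are rejected", {
  spec <- build_base_network(21, 10)
  expect_error(train_network(spec, list(), character(0),
                             toy$X[, , toy_va], toy$labels[toy_va],
                             train_config(max_iterations = 5)),
               "empty")
  expect_error(train_network(spec, toy$X[, , 1:4], rep("mi", 4),
                             toy$X[, , toy_va], toy$labels[toy_va],
                             train_config(max_iterations = 5)),
               "2 classes")
})

test_that("evaluate counts argmax agreements like a manual confusion count", {
  spec <- build_base_network(21, 10)
  fit <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                       toy$X[, , toy_va], toy$labels[toy_va],
                       train_config(max_iterations = 120, seed = 4))
  idx <- 41:50
  preds <- predict(fit, toy$X[, , idx])
  manual <- sum(preds$.pred_class == toy$labels[idx]) / length(idx)
  expect_equal(evaluate(fit, toy$X[, , idx], toy$labels[idx]), manual)
  expect_gte(manual, 0)
  expect_lte(manual, 1)
  # probabilities are consistent with the predicted class
  expect_true(all((preds$.prob_1 >= preds$.prob_2) ==
                    (preds$.pred_class == fit$classes[1])))
})

test_that("spatial filters have one weight per electrode per kernel", {
  spec <- build_base_network(21, 10)
  p <- init_parameters(spec, 21)
  fl <- extract_spatial_filters(spec, params = p)
  expect_equal(nrow(fl), 6L * 21L)
  expect_equal(dplyr::n_distinct(fl$filter), 6L)
  # round-trip: tidy weights match the seeded init draw
  expect_equal(matrix(fl$weight, 21, 6)[, 1], p$W1[1, ], ignore_attr = TRUE)

  cvp <- init_parameters(build_cv_network(), 3)
  flcv <- extract_spatial_filters(build_cv_network(), params = cvp)
  expect_equal(nrow(flcv), 6L * 49L)
})

test_that("broom methods expose history and a one-row summary", {
  spec <- build_base_network(21, 10)
  fit <- train_network(spec, toy$X[, , toy_tr], toy$labels[toy_tr],
                       toy$X[, , toy_va], toy$labels[toy_va],
                       train_config(max_iterations = 25, seed = 4))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 25L)
  expect_named(td, c("iteration", "loss", "train_accuracy", "val_accuracy"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$best_iteration, fit$best_iteration)
  expect_equal(gl$best_val_accuracy, max(td$val_accuracy))
})
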