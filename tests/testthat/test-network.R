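test_that("valid-padding convolution widths match the architecture arithmetic", {
  expect_equal(conv_output_width(10, 2, 2), 5L)
  expect_equal(conv_output_width(6, 3, 2), 2L)
  for (n in c(1, 5, 17)) expect_equal(conv_output_width(n, 1, 1), as.integer(n))
  expect_error(conv_output_width(4, 6, 1), "exceeds")
})

test_that("base architecture chains shapes as documented", {
  spec <- build_base_network(21, 10)
  expect_equal(spec$conv1_kernels, 6L)
  expect_equal(spec$conv1_width, 10L)       # 6 maps of 1 x 10
  expect_equal(spec$conv2_kernels, 12L)
  expect_equal(spec$conv2_out_width, 5L)    # 12 maps of 1 x 5
  expect_equal(spec$flatten_size, 60L)
  expect_equal(spec$hidden, 50L)
  expect_equal(spec$n_classes, 2L)

  spec49 <- build_base_network(49, 10)
  p <- init_parameters(spec49, 1)
  expect_equal(dim(p$W1), c(6L, 49L))       # C1 kernel 49 x 1

  expect_equal(build_base_network(8, 2)$conv2_out_width, 1L)
  expect_error(build_base_network(8, 1), "2 subbands")
})

test_that("cross-validation architecture reproduces the 49x6 shape chain", {
  spec <- build_cv_network(49, 6)
  expect_equal(spec$conv1_width, 6L)        # Conv_1 -> 1 x 6 x 6
  expect_equal(spec$conv1_kernels, 6L)
  expect_equal(spec$conv2_out_width, 2L)    # Conv_2 -> 1 x 2 x 12
  expect_equal(spec$conv2_kernels, 12L)
  expect_equal(spec$flatten_size, 24L)
  expect_equal(spec$hidden, c(50L, 100L, 200L))
  expect_equal(spec$conv1_activation, "elu")
  expect_error(build_cv_network(21, 10), "49, 6")
})

test_that("the first convolution is a pure spatial projection", {
  for (spec in list(build_base_network(21, 10), build_cv_network())) {
    p <- init_parameters(spec, 2)
    # kernel spans the full electrode axis and only one band position
    expect_equal(ncol(p$W1), spec$input_shape[1])
    expect_equal(nrow(p$W1), spec$conv1_kernels)
  }
})

test_that("activation functions satisfy their defining identities", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(relu(c(-3, 1.5))), relu(c(-3, 1.5)))
  expect_equal(relu(c(-5, -1)), c(0, 0))
  expect_equal(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1)
})

test_that("softmax is a shift-invariant probability map", {
  expect_equal(softmax(c(3, 3)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  z <- c(0.3, -1.2)
  expect_equal(softmax(z + 17.5), softmax(z))
  expect_equal(softmax(c(1000, 999)), softmax(c(1, 0)))  # max-shift stability
  set.seed(5)
  for (i in 1:20) {
    p <- softmax(rnorm(2, sd = 5))
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("cross-entropy matches closed forms and clips zero predictions", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(c(0, 1), c(0.5, 0.5)), log(2))
  expect_gt(cross_entropy(c(1, 0), c(0.9, 0.1)), 0)
  expect_warning(v <- cross_entropy(c(1, 0), c(0, 1)), "clipped")
  expect_equal(v, -log(1e-12))
})

test_that("dropout scales at inference and masks at the configured rate in training", {
  v <- c(1, -2, 3, 4)
  expect_equal(dropout(v, 0.5, "infer"), 0.5 * v)
  expect_equal(dropout(v, 0, "train"), v)
  expect_equal(dropout(v, 0, "infer"), v)
  expect_error(dropout(v, 1, "train"), "rate")

  set.seed(6)
  n_draw <- 2e4
  acc <- numeric(length(v))
  for (i in seq_len(n_draw)) acc <- acc + dropout(v, 0.3, "train")
  expect_equal(acc / n_draw, 0.7 * v, tolerance = 0.02)
})

test_that("initialization draws N(0, 0.1^2) weights and 0.1 biases, reproducibly", {
  spec <- build_cv_network()
  p <- init_parameters(spec, 11)
  expect_true(all(p$b1 == 0.1) && all(p$b2 == 0.1))
  for (b in p$bd) expect_true(all(b == 0.1))
  w <- c(p$W1, p$W2, unlist(p$Wd))
  expect_gt(length(w), 1e4)
  expect_lt(abs(sd(w) - 0.1), 0.005)
  expect_lt(abs(mean(w)), 0.005)
  expect_identical(init_parameters(spec, 11), p)
  expect_false(identical(init_parameters(spec, 12)$W1, p$W1))
})

test_that("forward pass yields valid probabilities and rejects shape mismatches", {
  spec <- build_base_network(8, 6)
  p <- init_parameters(spec, 3)
  zero <- p
  zero$W1[] <- 0; zero$W2[] <- 0
  zero$b1[] <- 0; zero$b2[] <- 0
  zero$Wd <- lapply(zero$Wd, function(W) W * 0)
  zero$bd <- lapply(zero$bd, function(b) b * 0)
  expect_equal(forward(spec, zero, matrix(rnorm(48), 8, 6)), c(0.5, 0.5))

  m <- matrix(rnorm(48), 8, 6)
  expect_identical(forward(spec, p, m), forward(spec, p, m))
  expect_error(forward(spec, p, matrix(0, 7, 6)), "shape")
})

test_that("vectorized forward pass agrees with the nested-loop oracle", {
  set.seed(7)
  specs <- list(build_base_network(8, 6), build_cv_network())
  for (spec in specs) {
    p <- init_parameters(spec, sample.int(1000, 1))
    for (r in 1:5) {
      m <- matrix(rnorm(prod(spec$input_shape)), spec$input_shape[1])
      expect_equal(forward(spec, p, m), oracle_forward(spec, p, m),
                   tolerance = 1e-10)
    }
  }
})
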