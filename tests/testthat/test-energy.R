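test_that("log-variance energy matches closed forms and the scale identity", {
  expect_equal(logvar_energy(c(-1, 1)), 0)            # population var 1
  expect_equal(logvar_energy(c(1, 2, 3, 4)), log(1.25))
  set.seed(1)
  y <- rnorm(500)
  expect_equal(logvar_energy(2 * y), logvar_energy(y) + 2 * log(2))
  expect_equal(logvar_energy(-3 * y), logvar_energy(y) + 2 * log(3))
})

test_that("zero-variance segments are floored with a warning", {
  expect_warning(v <- logvar_energy(rep(2, 10)), "floored")
  expect_equal(v, log(1e-12))
  expect_error(logvar_energy(1), "at least 2")
})

test_that("energy maps have channels x bands shape and symmetric rows", {
  fb <- make_filterbank(8, 30, 4, 2)
  tr <- raw_trial(matrix(rnorm(21 * 1000), 21), rate = 500, cue_index = 0)
  em <- energy_tensor(tr, fb)
  expect_equal(dim(em$values), c(21L, 10L))
  expect_false(em$normalized)

  one <- rnorm(1000)
  em2 <- energy_tensor(raw_trial(matrix(rep(one, each = 5), 5), 500), fb)
  for (ch in 2:5) expect_equal(em2$values[ch, ], em2$values[1, ])
})

test_that("the pipeline is deterministic: same trial, same map bits", {
  fb <- make_filterbank(8, 30, 4, 2)
  tr <- sine_trial()
  m1 <- transform_trial(tr, fb, c(0.5, 2.5))
  m2 <- transform_trial(tr, fb, c(0.5, 2.5))
  expect_identical(m1$values, m2$values)
})

test_that("z-score normalization matches hand-computed population values", {
  mk <- function(v) sfcnn:::new_energy_map(matrix(v, 1, 1), "ch", cbind(8, 12))
  two <- list(mk(0), mk(2))
  stats <- fit_normalization(two)
  normed <- vapply(two, function(m) apply_normalization(m, stats)$values[1, 1],
                   numeric(1))
  expect_equal(normed, c(-1, 1))

  three <- list(mk(1), mk(2), mk(3))
  s3 <- fit_normalization(three)
  z <- vapply(three, function(m) apply_normalization(m, s3)$values[1, 1],
              numeric(1))
  expect_equal(z, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-10)  # +/-1.2247
})

test_that("fit+apply on the fitting set gives cellwise mean 0 and sd 1", {
  set.seed(2)
  maps <- lapply(1:8, function(i) {
    sfcnn:::new_energy_map(matrix(rnorm(12, mean = 5), 3, 4),
                           sprintf("ch%d", 1:3), cbind(1:4, 2:5))
  })
  stats <- fit_normalization(maps)
  arr <- sfcnn:::maps_to_array(normalize_maps(maps, stats))
  expect_lt(max(abs(apply(arr, c(1, 2), mean))), 1e-6)
  expect_lt(max(abs(sqrt(apply(arr, c(1, 2), sfcnn:::pop_var)) - 1)), 1e-6)
  # idempotence: re-fitting on normalized maps finds mean ~0, sd ~1
  s2 <- fit_normalization(normalize_maps(maps, stats))
  expect_lt(max(abs(s2$mean)), 1e-6)
  expect_lt(max(abs(s2$sd - 1)), 1e-6)
})

test_that("degenerate cells get unit scale with a warning", {
  mk <- function(a, b) sfcnn:::new_energy_map(matrix(c(a, b), 1, 2), "ch",
                                              cbind(c(8, 10), c(12, 14)))
  expect_warning(stats <- fit_normalization(list(mk(3, 1), mk(3, 2))),
                 "degenerate")
  expect_equal(stats$sd[1, 1], 1)
  normed <- apply_normalization(mk(3, 1), stats)
  expect_equal(normed$values[1, 1], 0)
})

test_that("scaling a trial shifts unnormalized energies by 2 ln c and leaves normalized maps unchanged", {
  fb <- make_filterbank(8, 28, 4, 0)
  set.seed(3)
  trials <- lapply(1:4, function(i) {
    raw_trial(matrix(rnorm(2 * 1500), 2), rate = 500, cue_index = 100)
  })
  scaled <- lapply(trials, function(tr) {
    raw_trial(tr$data * 2.5, tr$rate, tr$cue_index)
  })
  w <- c(0.25, 2.25)
  maps <- lapply(trials, transform_trial, fb = fb, window = w)
  smaps <- lapply(scaled, transform_trial, fb = fb, window = w)
  for (i in 1:4) {
    expect_equal(smaps[[i]]$values, maps[[i]]$values + 2 * log(2.5),
                 tolerance = 1e-4)  # IIR recursion noise gain bounds exactness
  }
  n1 <- sfcnn:::maps_to_array(normalize_maps(maps))
  n2 <- sfcnn:::maps_to_array(normalize_maps(smaps))
  expect_equal(n1, n2, tolerance = 1e-4)
})

test_that("mismatched shapes are rejected by normalization", {
  a <- sfcnn:::new_energy_map(matrix(rnorm(4), 2, 2), c("a", "b"),
                              cbind(c(8, 10), c(12, 14)))
  b <- sfcnn:::new_energy_map(matrix(rnorm(6), 2, 3), c("a", "b"),
                              cbind(c(8, 10, 12), c(12, 14, 16)))
  stats <- suppressWarnings(fit_normalization(list(a, a, a)))
  expect_error(apply_normalization(b, stats), "does not match")
  expect_error(fit_normalization(list(a)), ">= 2 maps")
})
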