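# Small in-code fixtures shared across test files.

# Gaussian energy-map classes with a channel-coherent mean offset: class
# "mi" is shifted down across all bands of channel 9, mimicking the
# spatially localized, band-coherent ERD contrast the spatial-conv
# architecture is designed for.
toy_map_set <- function(n_per_class = 30, n_channels = 21, n_bands = 10,
                        offset = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- array(rnorm(n_channels * n_bands * n), c(n_channels, n_bands, n))
  labels <- rep(c("mi", "rest"), times = n_per_class)
  X[9, , labels == "mi"] <- X[9, , labels == "mi"] - offset
  list(X = X, labels = labels)
}

# A deterministic multi-sine trial useful for windowing/energy tests.
sine_trial <- function(n_channels = 3, rate = 250, duration = 4, cue_s = 1,
                       freq = 11, label = "rest") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  X <- t(sapply(seq_len(n_channels), function(ch) {
    ch * sin(2 * pi * freq * t + ch)
  }))
  raw_trial(X, rate = rate, cue_index = round(cue_s * rate), label = label)
}

# Tiny simulation spec (few channels, moderate rate) for fast pipeline tests.
tiny_sim_spec <- function(seed = 1, erd_depth = 0.6, ...) {
  sim_spec(n_channels = 6, rate = 250, duration = 3, cue_s = 0.5,
           erd_channels = 3L, erd_band = c(10, 14), erd_depth = erd_depth,
           rhythm_amplitude = 10, noise_scale = 3, seed = seed, ...)
}

tiny_run_config <- function(seed = 1) {
  config <- default_run_config()
  config$seed <- seed
  config$simulate <- list(n_channels = 6L, rate = 250, duration = 3,
                          cue_s = 0.5, erd_channels = 3L,
                          erd_band = c(10, 14), erd_depth = 0.6,
                          rhythm_amplitude = 10, noise_scale = 3,
                          noise_exponent = 1, n_per_class = 10L)
  config$preprocess$window <- c(0.5, 2.5)
  config$train$max_iterations <- 60L
  config$split <- list(mode = "fixed", n_train = 14L, n_test = 3L, n_val = 3L,
                       ordered = FALSE, folds = 4L)
  config
}
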