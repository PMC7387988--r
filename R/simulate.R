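#' Simulation specification for synthetic ERD-EEG
#'
#' Generative model of a two-class motor-imagery experiment: every channel
#' carries 1/f-shaped Gaussian background noise; designated sensorimotor
#' channels additionally carry a band-limited rhythm (narrowband-filtered
#' Gaussian noise, so per-trial band power fluctuates realistically). After
#' the cue, the rhythm amplitude on those channels is attenuated by
#' `erd_depth` in the motor-imagery class — event-related desynchronization —
#' while the pre-cue segment is distributed identically in both classes.
#'
#' The defaults mirror a 21-electrode finger-imagery recording: 1000 Hz,
#' 4-s trials with the cue at 1 s, a mu rhythm at 10--14 Hz on one
#' contralateral "C3-like" channel (index 9), 10 uV rhythm over 5 uV
#' background with spectral slope 1, and 50% post-cue attenuation.
#'
#' @param n_channels Electrode count.
#' @param rate Sampling rate, Hz.
#' @param duration Trial length, seconds.
#' @param cue_s Cue onset, seconds from trial start.
#' @param erd_channels Channel indices carrying the rhythm.
#' @param erd_band Rhythm band (lo, hi), Hz.
#' @param erd_depth Post-cue attenuation fraction in `[0, 1)` for the MI class.
#' @param rhythm_amplitude Rhythm standard deviation, uV.
#' @param noise_scale Background standard deviation, uV.
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^exp).
#' @param mixing Optional channels x channels mixing matrix applied to the
#'   clean multichannel signal (volume-conduction stand-in); `NULL` = none.
#' @param seed Master seed; each trial derives an independent substream.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_channels = 21L, rate = 1000, duration = 4, cue_s = 1,
                     erd_channels = 9L, erd_band = c(10, 14), erd_depth = 0.5,
                     rhythm_amplitude = 10, noise_scale = 5,
                     noise_exponent = 1, mixing = NULL, seed = 1L) {
  if (any(erd_channels < 1L) || any(erd_channels > n_channels)) {
    stop_sfcnn("erd_channels must lie in 1..", n_channels)
  }
  if (erd_band[1] <= 0 || erd_band[2] <= erd_band[1] || erd_band[2] >= rate / 2) {
    stop_sfcnn("erd_band must satisfy 0 < lo < hi < Nyquist")
  }
  if (erd_depth < 0 || erd_depth >= 1) stop_sfcnn("erd_depth must be in [0, 1)")
  if (cue_s < 0 || cue_s >= duration) stop_sfcnn("cue_s must be in [0, duration)")
  structure(list(n_channels = as.integer(n_channels), rate = rate,
                 duration = duration, cue_s = cue_s,
                 erd_channels = as.integer(erd_channels),
                 erd_band = erd_band, erd_depth = erd_depth,
                 rhythm_amplitude = rhythm_amplitude,
                 noise_scale = noise_scale, noise_exponent = noise_exponent,
                 mixing = mixing, seed = as.integer(seed)),
            class = "sim_spec")
}

# 1/f^(exponent) Gaussian background, unit sd, via spectral shaping of white
# noise (amplitude spectrum scaled by f^(-exponent/2), DC removed).
pink_noise <- function(n, rate, exponent) {
  z <- rnorm(n)
  if (exponent == 0) return(z)
  Z <- stats::fft(z)
  f <- c(1, seq_len(n - 1))  # bin 1 is DC
  f <- pmin(f, n - f + 1)    # fold to two-sided frequencies
  scale <- c(0, (f[-1] * rate / n)^(-exponent / 2))
  x <- Re(stats::fft(Z * scale, inverse = TRUE)) / n
  x / sqrt(pop_var(x))
}

# Unit-sd narrowband rhythm: white noise bandpassed to `band`.
narrowband_rhythm <- function(n, rate, band) {
  x <- bandpass(rnorm(n), band, rate)
  x / sqrt(pop_var(x))
}

#' Simulate one labeled EEG trial
#'
#' @param spec A [sim_spec()].
#' @param label `"mi"` or `"rest"`.
#' @param seed Seed for this trial's draw (defaults to the spec seed).
#' @return A [raw_trial()] of `n_channels x duration * rate` samples with
#'   the cue index set from `cue_s`.
#' @export
simulate_trial <- function(spec, label = c("mi", "rest"), seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  label <- match.arg(label)
  set.seed(as.integer(seed))
  n <- round(spec$duration * spec$rate)
  cue <- round(spec$cue_s * spec$rate)
  X <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    X[ch, ] <- spec$noise_scale * pink_noise(n, spec$rate, spec$noise_exponent)
  }
  post <- (cue + 1):n
  envelope <- rep(spec$rhythm_amplitude, n)
  if (label == "mi") {
    envelope[post] <- spec$rhythm_amplitude * (1 - spec$erd_depth)
  }
  for (ch in spec$erd_channels) {
    X[ch, ] <- X[ch, ] + envelope * narrowband_rhythm(n, spec$rate, spec$erd_band)
  }
  if (!is.null(spec$mixing)) X <- spec$mixing %*% X
  raw_trial(X, rate = spec$rate, cue_index = cue, label = label)
}

#' Simulate a balanced labeled dataset
#'
#' Trials are drawn independently: trial `i` uses a substream seed derived
#' from the spec's master seed, so the dataset is reproducible as a whole
#' and any single trial is reproducible in isolation. MI and rest trials
#' alternate in the returned list.
#'
#' @param spec A [sim_spec()].
#' @param n_per_class Trials per class.
#' @return List of `2 * n_per_class` [raw_trial()]s with a `labels`
#'   attribute.
#' @export
simulate_dataset <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "sim_spec"), n_per_class >= 1L)
  labels <- rep(c("mi", "rest"), times = n_per_class)
  trials <- lapply(seq_along(labels), function(i) {
    simulate_trial(spec, labels[i],
                   seed = substream_seed(spec$seed, paste0("trial-", i)))
  })
  attr(trials, "labels") <- labels
  trials
}

#' Expected MI-minus-rest log-variance gap at the ERD cell
#'
#' In the noiseless-rhythm limit the post-cue rhythm variance scales with the
#' squared amplitude, so attenuating the amplitude by `1 - depth` shifts the
#' log-variance energy by exactly `2 * ln(1 - depth)` — the closed-form
#' oracle for the class contrast the decoder must pick up.
#'
#' @param depth Attenuation fraction in `[0, 1)`.
#' @return `2 * log(1 - depth)` (non-positive).
#' @examples
#' theoretical_logvar_gap(0.5)  # 2 * ln(0.5)
#' @export
theoretical_logvar_gap <- function(depth) {
  if (any(depth < 0) || any(depth >= 1)) stop_sfcnn("depth must be in [0, 1)")
  2 * log(1 - depth)
}
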