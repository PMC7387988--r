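#' Log-variance band power of a signal segment
#'
#' The scalar energy feature `p = ln(var(x))`, with the population variance
#' (divide by N). Scaling the signal by `c` shifts the energy by exactly
#' `2 * ln(|c|)`. Zero-variance segments are floored at `ln(eps)` with a
#' warning rather than returning `-Inf`.
#'
#' @param x Numeric vector, length >= 2.
#' @param eps Variance floor (default 1e-12).
#' @return A single number, `ln(max(var_pop(x), eps))`.
#' @examples
#' logvar_energy(c(1, 2, 3, 4))  # ln(1.25)
#' @export
logvar_energy <- function(x, eps = 1e-12) {
  if (length(x) < 2L) stop_sfcnn("need at least 2 samples for a variance")
  v <- pop_var(x)
  if (v < eps) {
    warning("zero-variance segment: log energy floored at ln(", eps, ")")
    v <- eps
  }
  log(v)
}

pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

# Column-wise population variance of a time x channels matrix.
col_pop_var <- function(X) {
  m <- colMeans(X)
  colMeans((X - rep(m, each = nrow(X)))^2)
}

new_energy_map <- function(values, channel_names, band_edges, normalized = FALSE) {
  dimnames(values) <- list(channel_names,
                           sprintf("%g-%g", band_edges[, 1], band_edges[, 2]))
  structure(
    list(values = values, channel_names = channel_names,
         band_edges = band_edges, normalized = normalized),
    class = "energy_map"
  )
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("<energy_map> %d channels x %d bands (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "unnormalized"))
  print(utils::head(round(x$values, 3), 6))
  invisible(x)
}

#' Spatial-frequency energy map of a (windowed) trial
#'
#' For every (channel, subband) cell, bandpass-filters the channel and takes
#' the log-variance energy of the result, yielding the channels-by-bands
#' "image" the networks classify. Electrodes index the rows (vertical axis),
#' subbands the columns (horizontal axis). The trial is used as given; see
#' [transform_trial()] for the full filter-then-window pipeline.
#'
#' @param trial A [raw_trial()], typically already windowed.
#' @param fb A [make_filterbank()] specification.
#' @return An `energy_map` (unnormalized).
#' @export
energy_tensor <- function(trial, fb) {
  stopifnot(inherits(trial, "raw_trial"), inherits(fb, "filterbank"))
  Xt <- t(trial$data)  # time x channels
  vals <- vapply(seq_len(fb$n_bands), function(j) {
    coef <- band_coefficients(fb$bands[j, ], trial$rate)
    npad <- band_pad_length(fb$bands[j, ], trial$rate)
    Xf <- reflect_filtfilt(Xt, coef, npad)
    log(pmax(col_pop_var(Xf), 1e-12))
  }, numeric(nrow(trial$data)))
  new_energy_map(matrix(vals, nrow = nrow(trial$data)),
                 trial$channel_names, fb$bands)
}

#' Transform a raw trial into its energy map
#'
#' The standard pipeline order: the full-length trial is bandpass-filtered in
#' every subband first, then the cue-locked window is cut from the filtered
#' signal (so filter edge transients fall outside the analysis window), and
#' the log-variance energy is taken per cell.
#'
#' @param trial An unwindowed [raw_trial()] with a valid cue index.
#' @param fb A [make_filterbank()].
#' @param window Length-2 numeric, window in seconds after the cue
#'   (default `c(0.5, 2.5)`).
#' @return An `energy_map` (unnormalized).
#' @export
transform_trial <- function(trial, fb, window = c(0.5, 2.5)) {
  stopifnot(inherits(trial, "raw_trial"), inherits(fb, "filterbank"))
  i0 <- trial$cue_index + round(window[1] * trial$rate)
  i1 <- trial$cue_index + round(window[2] * trial$rate)
  if (i0 < 0 || i1 > ncol(trial$data)) {
    stop_sfcnn("window [", i0, ", ", i1, ") exceeds trial of ",
               ncol(trial$data), " timepoints")
  }
  Xt <- t(trial$data)
  rows <- (i0 + 1):i1
  vals <- vapply(seq_len(fb$n_bands), function(j) {
    coef <- band_coefficients(fb$bands[j, ], trial$rate)
    npad <- band_pad_length(fb$bands[j, ], trial$rate)
    Xf <- reflect_filtfilt(Xt, coef, npad)[rows, , drop = FALSE]
    log(pmax(col_pop_var(Xf), 1e-12))
  }, numeric(nrow(trial$data)))
  new_energy_map(matrix(vals, nrow = nrow(trial$data)),
                 trial$channel_names, fb$bands)
}

#' Transform a list of trials into energy maps
#'
#' @param trials List of [raw_trial()] objects with identical geometry.
#' @param fb A [make_filterbank()].
#' @param window Analysis window in seconds after the cue.
#' @param channels Optional channel-index vector passed to
#'   [select_channels()] before transforming.
#' @return List of `energy_map` objects (unnormalized), with trial labels
#'   preserved in `attr(, "labels")`.
#' @export
transform_dataset <- function(trials, fb, window = c(0.5, 2.5), channels = NULL) {
  maps <- lapply(trials, function(tr) {
    if (!is.null(channels)) tr <- select_channels(tr, channels)
    transform_trial(tr, fb, window)
  })
  attr(maps, "labels") <- vapply(trials, function(tr) tr$label, character(1))
  maps
}

#' Fit per-cell normalization statistics
#'
#' Computes, for every (channel, band) cell, the mean and population standard
#' deviation of the energy across the supplied maps, for z-score
#' normalization of each cell. Cells whose standard deviation falls below
#' `min_sd` are degenerate (no variation across samples); their scale is set
#' to 1 with a warning so normalization leaves them centred but unscaled.
#'
#' @param maps List of `energy_map`s of identical shape (>= 2).
#' @param min_sd Degeneracy threshold for the per-cell standard deviation.
#' @return A `normalization_stats` object with `$mean`, `$sd`, `$n_fit`.
#' @export
fit_normalization <- function(maps, min_sd = 1e-8) {
  if (length(maps) < 2L) stop_sfcnn("need >= 2 maps to fit normalization")
  arr <- maps_to_array(maps)
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- sqrt(apply(arr, c(1, 2), pop_var))
  if (any(sd_ < min_sd)) {
    warning(sum(sd_ < min_sd), " degenerate cell(s): sd below ", min_sd,
            ", scale set to 1")
    sd_[sd_ < min_sd] <- 1
  }
  structure(list(mean = mu, sd = sd_, n_fit = length(maps)),
            class = "normalization_stats")
}

#' Apply normalization statistics to an energy map
#'
#' @param map An `energy_map`.
#' @param stats A `normalization_stats` from [fit_normalization()].
#' @return The z-scored `energy_map` (`normalized = TRUE`).
#' @export
apply_normalization <- function(map, stats) {
  stopifnot(inherits(map, "energy_map"), inherits(stats, "normalization_stats"))
  if (!all(dim(map$values) == dim(stats$mean))) {
    stop_sfcnn("map shape ", paste(dim(map$values), collapse = "x"),
               " does not match stats shape ",
               paste(dim(stats$mean), collapse = "x"))
  }
  new_energy_map((map$values - stats$mean) / stats$sd,
                 map$channel_names, map$band_edges, normalized = TRUE)
}

#' Normalize a list of energy maps with given (or freshly fitted) statistics
#'
#' @param maps List of `energy_map`s.
#' @param stats Optional `normalization_stats`; fitted on `maps` when `NULL`.
#' @return List of normalized maps, labels attribute preserved.
#' @export
normalize_maps <- function(maps, stats = NULL) {
  stats <- stats %||% fit_normalization(maps)
  out <- lapply(maps, apply_normalization, stats = stats)
  attr(out, "labels") <- attr(maps, "labels")
  out
}

# channels x bands x n array from a list of maps (or pass-through array)
maps_to_array <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3L) return(maps)
  if (length(maps) == 0L) stop_sfcnn("empty set of energy maps")
  d <- dim(maps[[1]]$values)
  bad <- which(vapply(maps, function(m) !all(dim(m$values) == d), logical(1)))
  if (length(bad)) stop_sfcnn("map ", bad[1], " has a different shape")
  array(unlist(lapply(maps, function(m) m$values)), dim = c(d, length(maps)))
}

#' @exportS3Method
as_tibble.energy_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channel_names, times = ncol(x$values)),
    band_lo = rep(x$band_edges[, 1], each = nrow(x$values)),
    band_hi = rep(x$band_edges[, 2], each = nrow(x$values)),
    energy = as.numeric(x$values)
  )
}
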