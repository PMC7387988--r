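#' Build an overlapping bandpass filterbank specification
#'
#' Tiles the frequency range `[low, high]` with subbands of equal `width`
#' whose consecutive lower edges advance by `width - overlap`. The canonical
#' sensorimotor configuration, `make_filterbank(8, 30, 4, 2)`, produces the
#' ten 4-Hz bands (8,12), (10,14), ..., (26,30) covering the mu and beta
#' rhythms; `make_filterbank(4, 40, 6, 0)` gives six non-overlapping 6-Hz
#' bands.
#'
#' @param low,high Range covered, Hz.
#' @param width Subband width, Hz.
#' @param overlap Overlap between adjacent subbands, Hz (`0 <= overlap < width`).
#' @return A `filterbank` object; `$bands` is an n-by-2 matrix of (lo, hi)
#'   edges in Hz.
#' @examples
#' make_filterbank(8, 30, 4, 2)
#' @export
make_filterbank <- function(low, high, width, overlap = 0) {
  if (width <= 0 || overlap < 0 || overlap >= width) {
    stop_sfcnn("need width > overlap >= 0")
  }
  if (high - low < width) stop_sfcnn("range narrower than one band")
  step <- width - overlap
  residual <- (high - low - width) %% step
  if (abs(residual) > 1e-9 && abs(residual - step) > 1e-9) {
    stop_sfcnn("bands do not tile [", low, ", ", high, "]: residual of ",
               signif(residual, 6), " Hz remains with step ", step, " Hz")
  }
  n_bands <- as.integer(round((high - low - width) / step)) + 1L
  lo <- low + step * (seq_len(n_bands) - 1)
  bands <- cbind(lo = lo, hi = lo + width)
  structure(
    list(low = low, high = high, width = width, overlap = overlap,
         bands = bands, n_bands = n_bands),
    class = "filterbank"
  )
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("<filterbank> %d bands of %g Hz (overlap %g Hz) covering %g-%g Hz\n",
              x$n_bands, x$width, x$overlap, x$low, x$high))
  cat(paste(sprintf("(%g,%g)", x$bands[, 1], x$bands[, 2]), collapse = " "), "\n")
  invisible(x)
}

# Butterworth coefficients for one subband; cached per (band, rate) within a
# call site by the caller when filtering many trials.
band_coefficients <- function(band, rate, order = 4L) {
  lo <- band[[1]]; hi <- band[[2]]
  nyq <- rate / 2
  if (lo <= 0 || hi <= lo || hi >= nyq) {
    stop_sfcnn("band (", lo, ", ", hi, ") Hz must satisfy 0 < lo < hi < Nyquist (",
               nyq, " Hz)")
  }
  signal::butter(order, c(lo, hi) / nyq, type = "pass")
}

# One-direction IIR pass on a timepoints x series matrix, identical to
# signal::filter's use of stats::filter (convolution numerator + recursive
# denominator) but vectorized over columns.
iir_pass <- function(X, b, a) {
  nb <- length(b)
  Z <- stats::filter(rbind(matrix(0, nb - 1L, ncol(X)), X),
                     filt = b, method = "convolution", sides = 1)
  Z <- Z[nb:nrow(Z), , drop = FALSE]
  Y <- stats::filter(Z, filt = -a[-1], method = "recursive")
  matrix(as.numeric(Y), nrow(X), ncol(X))
}

# Zero-phase forward-backward pass replicating signal::filtfilt's padding
# (2 * filter length of trailing zeros before each direction); agreement with
# signal::filtfilt is bit-exact and covered by a unit test.
filtfilt_matrix <- function(X, coef) {
  b <- coef$b; a <- coef$a
  n <- nrow(X); npad <- 2L * max(length(a), length(b))
  pad <- matrix(0, npad, ncol(X))
  Y <- iir_pass(rbind(X, pad), b, a)
  Y <- iir_pass(Y[nrow(Y):1, , drop = FALSE], b, a)
  Y[nrow(Y):1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

# Odd-reflection padding before the forward-backward pass: the signal is
# extended at both ends by its time-reversed, sign-flipped continuation so
# the filter sees no step discontinuity. The pad length covers several ring
# times of the narrowest practical band (~3 / bandwidth seconds).
reflect_filtfilt <- function(X, coef, npad) {
  n <- nrow(X)
  npad <- min(npad, n - 1L)
  if (npad > 0L) {
    head_pad <- 2 * rep(X[1, ], each = npad) - X[(npad + 1):2, , drop = FALSE]
    tail_pad <- 2 * rep(X[n, ], each = npad) - X[(n - 1):(n - npad), , drop = FALSE]
    Xp <- rbind(head_pad, X, tail_pad)
  } else {
    Xp <- X
  }
  filtfilt_matrix(Xp, coef)[npad + seq_len(n), , drop = FALSE]
}

#' Zero-phase bandpass filter a signal
#'
#' Applies a 4th-order Butterworth bandpass forward and backward (zero phase
#' shift, so band-power estimates downstream are unaffected by filter delay).
#' The signal is edge-padded by odd reflection before filtering so that
#' filter transients at the ends are strongly suppressed.
#'
#' @param x Numeric vector (one channel's timecourse) or a channels-by-time
#'   matrix, filtered row-wise.
#' @param band Length-2 numeric, (lo, hi) passband edges in Hz.
#' @param rate Sampling rate in Hz; `hi` must be below `rate / 2`.
#' @param order Butterworth order (default 4).
#' @return Filtered data with the same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' y <- bandpass(sin(2 * pi * 11 * t), c(8, 12), rate = 250)
#' @export
bandpass <- function(x, band, rate, order = 4L) {
  coef <- band_coefficients(band, rate, order)
  npad <- band_pad_length(band, rate)
  if (is.matrix(x)) {
    out <- t(reflect_filtfilt(t(x), coef, npad))
    dimnames(out) <- dimnames(x)
    out
  } else {
    as.numeric(reflect_filtfilt(matrix(as.numeric(x), ncol = 1L), coef, npad))
  }
}

# ~3 ring times of the band's impulse response
band_pad_length <- function(band, rate) {
  as.integer(round(3 * rate / max(band[[2]] - band[[1]], 1e-9)))
}
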