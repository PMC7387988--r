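#' Construct a raw EEG trial
#'
#' A trial is one epoched segment of multichannel EEG: a channels-by-timepoints
#' amplitude matrix (microvolts) together with its sampling rate, the sample
#' index of the visual cue, and an optional class label.
#'
#' @param data Numeric matrix, channels in rows, timepoints in columns.
#' @param rate Sampling frequency in Hz.
#' @param cue_index 0-based sample index of cue onset (0 means the trial
#'   starts at the cue). Windows are taken relative to this index.
#' @param label Class label (e.g. `"mi"` or `"rest"`), or `NA`.
#' @param channel_names Character vector of electrode labels; defaults to
#'   `ch01, ch02, ...`.
#'
#' @return An object of class `raw_trial`.
#' @examples
#' tr <- raw_trial(matrix(rnorm(21 * 400), 21), rate = 100, cue_index = 50)
#' tr
#' @export
raw_trial <- function(data, rate, cue_index = 0L, label = NA_character_,
                      channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop_sfcnn("trial data must be a finite numeric matrix")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_sfcnn("rate must be a single positive number (Hz)")
  }
  cue_index <- as.integer(cue_index)
  if (cue_index < 0L || cue_index >= ncol(data)) {
    stop_sfcnn("cue_index must satisfy 0 <= cue_index < timepoints, got ",
               cue_index, " with ", ncol(data), " timepoints")
  }
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data)) {
    stop_sfcnn("channel_names length (", length(channel_names),
               ") must equal channel count (", nrow(data), ")")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, rate = rate, cue_index = cue_index,
         label = as.character(label), channel_names = channel_names),
    class = "raw_trial"
  )
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %d channels x %d timepoints @ %g Hz, cue at %d, label %s\n",
              nrow(x$data), ncol(x$data), x$rate, x$cue_index, x$label))
  invisible(x)
}

#' Extract a cue-locked analysis window from a trial
#'
#' Slices the half-open window `[cue + start_s * rate, cue + end_s * rate)`
#' (0-based sample indices, bounds rounded to the nearest sample) so a
#' 0.5--2.5 s window at 1000 Hz yields exactly 2000 samples per channel. The
#' returned trial has its cue index reset to 0.
#'
#' @param trial A [raw_trial()].
#' @param start_s,end_s Window bounds in seconds after the cue.
#' @return A [raw_trial()] holding the windowed data.
#' @examples
#' tr <- raw_trial(matrix(rnorm(2 * 1000), 2), rate = 250, cue_index = 100)
#' win <- extract_window(tr, 0.5, 2.5)
#' ncol(win$data)  # 500
#' @export
extract_window <- function(trial, start_s, end_s) {
  stopifnot(inherits(trial, "raw_trial"))
  if (start_s >= end_s) stop_sfcnn("start_s must be < end_s")
  i0 <- trial$cue_index + round(start_s * trial$rate)
  i1 <- trial$cue_index + round(end_s * trial$rate)
  if (i0 < 0 || i1 > ncol(trial$data)) {
    stop_sfcnn("window [", i0, ", ", i1, ") exceeds trial of ",
               ncol(trial$data), " timepoints")
  }
  raw_trial(trial$data[, (i0 + 1):i1, drop = FALSE], rate = trial$rate,
            cue_index = 0L, label = trial$label,
            channel_names = trial$channel_names)
}

#' Select and reorder channels of a trial
#'
#' @param trial A [raw_trial()].
#' @param indices Integer vector of channel indices (1-based, unique); the
#'   output follows this order.
#' @return A [raw_trial()] restricted to the requested channels.
#' @export
select_channels <- function(trial, indices) {
  stopifnot(inherits(trial, "raw_trial"))
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > nrow(trial$data))) {
    stop_sfcnn("channel indices out of range 1..", nrow(trial$data))
  }
  if (anyDuplicated(indices)) stop_sfcnn("channel indices must be unique")
  raw_trial(trial$data[indices, , drop = FALSE], rate = trial$rate,
            cue_index = trial$cue_index, label = trial$label,
            channel_names = trial$channel_names[indices])
}
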