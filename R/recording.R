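#' Multi-channel EEG recording container
#'
#' An `eeg_recording` holds a continuous multi-channel EEG signal as a
#' channels-by-samples matrix (microvolts), its sampling rate, and montage
#' channel labels (10-20 names such as `"Fp1"`, `"Cz"` where applicable).
#'
#' @param samples numeric matrix, C channels x N samples, all finite.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of length C with unique labels;
#'   defaults to `"Ch1"..."ChC"`.
#' @return An object of class `eeg_recording` with fields `samples`, `fs`,
#'   `channel_labels`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), 2, 256), fs = 256)
#' rec
#' @export
eeg_recording <- function(samples, fs, channel_labels = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("recording must have at least one channel and one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("recording samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(samples)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("`channel_labels` must have one entry per channel", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  structure(
    list(samples = unname(samples), fs = as.numeric(fs),
         channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

#' Labelled fixed-length EEG epochs
#'
#' An `eeg_epochs` object holds fixed-length windows cut from a continuous
#' recording as an epochs x channels x samples array, plus the sampling
#' rate, window length, window start times and (optionally) one class label
#' per epoch.
#'
#' @param epochs numeric array E x C x L.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (L = window_s * fs samples).
#' @param start_times numeric vector of E window start times in seconds,
#'   strictly increasing within a recording.
#' @param labels optional factor/character of length E with per-epoch class
#'   labels.
#' @param channel_labels optional character vector of C channel labels.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs, window_s, start_times = NULL,
                       labels = NULL, channel_labels = NULL) {
  if (!is.array(epochs) || length(dim(epochs)) != 3L)
    stop("`epochs` must be a 3-d array (epochs x channels x samples)", call. = FALSE)
  d <- dim(epochs)
  if (!is.null(start_times) && length(start_times) != d[1L])
    stop("`start_times` must have one entry per epoch", call. = FALSE)
  if (is.null(start_times)) start_times <- (seq_len(d[1L]) - 1) * window_s
  if (!is.null(labels)) {
    if (length(labels) != d[1L])
      stop("`labels` must have one entry per epoch", call. = FALSE)
    labels <- factor(labels)
  }
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(d[2L]))
  structure(
    list(epochs = epochs, fs = as.numeric(fs), window_s = as.numeric(window_s),
         start_times = as.numeric(start_times), labels = labels,
         channel_labels = as.character(channel_labels)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$window_s, x$fs))
  if (!is.null(x$labels))
    print(table(labels = x$labels))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$epochs)

n_epochs <- function(x) dim(x$epochs)[1L]

#' Subset epochs
#'
#' @param x an `eeg_epochs` object.
#' @param i integer or logical index over epochs.
#' @param ... ignored.
#' @return An `eeg_epochs` object with the selected epochs.
#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  eeg_epochs(x$epochs[i, , , drop = FALSE], x$fs, x$window_s,
             x$start_times[i],
             if (!is.null(x$labels)) x$labels[i, drop = FALSE] else NULL,
             x$channel_labels)
}
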