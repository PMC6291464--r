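#' Construct an EEG recording object
#'
#' Container for a multichannel recording: a channels x samples matrix of
#' amplitudes in microvolts, sampling rate, unique channel labels and an
#' optional condition tag.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (muV).
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel names, one per row.
#'   Defaults to rownames of `data`, else `ch01`, `ch02`, ...
#' @param condition Optional condition tag, one of `"rest"`, `"0-back"`,
#'   `"2-back"` or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100)
#' rec
eeg_recording <- function(data, fs, labels = NULL, condition = NA_character_) {
  stop_if_not(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  stop_if_not(is.numeric(fs) && length(fs) == 1 && fs > 0, "`fs` must be a positive scalar")
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  stop_if_not(length(labels) == nrow(data), "label count must equal channel (row) count")
  stop_if_not(!anyDuplicated(labels), "channel labels must be unique")
  if (!is.na(condition))
    stop_if_not(condition %in% c("rest", "0-back", "2-back"),
                "condition must be one of rest, 0-back, 2-back")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.na(x$condition)) "" else paste0(", condition: ", x$condition)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An [eeg_recording].
#' @return Scalar duration in seconds.
#' @export
recording_duration <- function(recording) ncol(recording$data) / recording$fs
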