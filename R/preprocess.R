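#' Define a frequency band
#'
#' @param name Band name (e.g. `"theta"`).
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `band_definition`.
#' @export
#' @examples
#' band_definition("theta", 4, 8)
band_definition <- function(name, low, high) {
  stop_if_not(is.character(name) && length(name) == 1, "`name` must be a string")
  stop_if_not(is.numeric(low) && is.numeric(high) && low > 0 && high > low,
              "band edges must satisfy 0 < low < high")
  structure(list(name = name, low = low, high = high), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Design a windowed-sinc band-pass FIR filter
#'
#' Hamming-windowed ideal band-pass impulse response. The number of taps
#' follows the ~3.3 transition-width heuristic for the Hamming window,
#' `ntaps = ceil(3.3 * fs / trans)`, forced odd so the filter is exactly
#' linear phase (type I). The kernel is rescaled to unit gain at the
#' geometric band centre.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz; `high` must be below `fs / 2`.
#' @param trans Transition width in Hz; default `min(2, 0.25 * low)`.
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @export
fir_bandpass <- function(low, high, fs, trans = NULL) {
  stop_if_not(high < fs / 2, "band exceeds the Nyquist frequency")
  stop_if_not(low > 0 && high > low, "invalid band edges")
  if (is.null(trans)) trans <- min(2, 0.25 * low)
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  n <- seq(-m, m)
  f1 <- low / fs
  f2 <- high / fs
  h <- ifelse(n == 0, 2 * (f2 - f1),
              (sin(2 * pi * f2 * n) - sin(2 * pi * f1 * n)) / (pi * n))
  w <- 0.54 + 0.46 * cos(pi * n / m)  # Hamming, peak at centre tap
  h <- h * w
  fc <- sqrt(low * high)
  gain <- abs(sum(h * exp(-2i * pi * fc / fs * n)))
  h / gain
}

# One delay-compensated FIR pass over the rows of `mat`, with odd-symmetric
# edge reflection padding to suppress boundary transients. Kernel must be
# symmetric (linear phase).
fir_pass <- function(mat, h) {
  n <- ncol(mat)
  L <- length(h)
  d <- (L - 1) / 2
  pad <- min(L, n - 1)
  left <- 2 * mat[, 1] - mat[, seq(pad + 1, 2), drop = FALSE]
  right <- 2 * mat[, n] - mat[, seq(n - 1, n - pad), drop = FALSE]
  xe <- cbind(left, mat, right)
  m <- ncol(xe)
  nfft <- 2^ceiling(log2(m + L - 1))
  H <- fft(c(h, numeric(nfft - L)))
  X <- mvfft(t(cbind(xe, matrix(0, nrow(xe), nfft - m))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  y <- t(y)[, (d + 1):(d + m), drop = FALSE]
  y[, (pad + 1):(pad + n), drop = FALSE]
}

# Forward-backward (two-pass) zero-phase filtering of a channels x samples
# matrix. With a symmetric kernel the backward pass squares the magnitude
# response and leaves the phase untouched.
fir_filtfilt <- function(mat, h) {
  y <- fir_pass(mat, h)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- fir_pass(y, h)
  y[, rev(seq_len(ncol(y))), drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Applies a windowed-sinc FIR band-pass forwards and backwards (zero net
#' phase shift). Works on a whole [eeg_recording] or on an epoch set
#' produced by [extract_epochs()].
#'
#' @param x An [eeg_recording] or `eeg_epochs` object.
#' @param band A [band_definition].
#' @param trans Optional transition width override in Hz.
#' @return Object of the same class with filtered data and a `band`
#'   attribute recording the band name.
#' @export
bandpass_filter <- function(x, band, trans = NULL) UseMethod("bandpass_filter")

#' @export
bandpass_filter.eeg_recording <- function(x, band, trans = NULL) {
  stop_if_not(inherits(band, "band_definition"), "`band` must be a band_definition")
  h <- fir_bandpass(band$low, band$high, x$fs, trans)
  out <- x
  out$data <- fir_filtfilt(x$data, h)
  rownames(out$data) <- x$labels
  attr(out, "band") <- band$name
  out
}

#' @export
bandpass_filter.eeg_epochs <- function(x, band, trans = NULL) {
  stop_if_not(inherits(band, "band_definition"), "`band` must be a band_definition")
  h <- fir_bandpass(band$low, band$high, x$fs, trans)
  out <- x
  out$epochs <- lapply(x$epochs, fir_filtfilt, h = h)
  out$band <- band$name
  out
}

#' Cut fixed-length epochs at stimulus onsets
#'
#' Each epoch starts at the sample nearest the requested onset and spans
#' `epoch_len` seconds. Onsets whose epoch would run past the end of the
#' recording are skipped with a warning.
#'
#' @param recording An [eeg_recording].
#' @param onsets Numeric vector of onset times in seconds.
#' @param epoch_len Epoch length in seconds (default 3.5).
#' @return An `eeg_epochs` object: list of channels x samples matrices plus
#'   `fs`, `labels`, `condition`, `band` and the indices of skipped onsets.
#' @export
extract_epochs <- function(recording, onsets, epoch_len = 3.5) {
  stop_if_not(inherits(recording, "eeg_recording"), "`recording` must be an eeg_recording")
  nsamp <- round(epoch_len * recording$fs)
  total <- ncol(recording$data)
  starts <- round(onsets * recording$fs) + 1
  ok <- starts >= 1 & (starts + nsamp - 1) <= total
  if (any(!ok))
    warning(sprintf("%d onset(s) outside the recording were skipped", sum(!ok)))
  eps <- lapply(starts[ok], function(s)
    recording$data[, s:(s + nsamp - 1), drop = FALSE])
  structure(list(epochs = eps, fs = recording$fs, labels = recording$labels,
                 condition = recording$condition, band = attr(recording, "band"),
                 skipped = which(!ok)),
            class = "eeg_epochs")
}

#' Onsets for consecutive resting-state pseudo-epochs
#'
#' Continuous (resting) data carry no stimulus events; they are sliced into
#' consecutive, non-overlapping epochs of `epoch_len` seconds starting at
#' time zero.
#'
#' @param recording An [eeg_recording].
#' @param epoch_len Epoch length in seconds (default 3.5).
#' @return Numeric vector of onset times in seconds.
#' @export
#' @examples
#' # 300 s of rest yields floor(300 / 3.5) = 85 pseudo-epochs
rest_onsets <- function(recording, epoch_len = 3.5) {
  k <- floor(recording_duration(recording) / epoch_len)
  if (k < 1) return(numeric(0))
  epoch_len * (seq_len(k) - 1)
}

#' Reject high-amplitude epochs
#'
#' An epoch is removed iff its maximal absolute amplitude over all channels
#' and samples exceeds the threshold (strictly greater than).
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold_uv Rejection threshold in microvolts (default 60).
#' @return The retained `eeg_epochs`, with a `report` data frame attached
#'   (`attr(, "report")`) listing removed epoch indices, the offending
#'   channel and the peak amplitude.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 60) {
  stop_if_not(inherits(epochs, "eeg_epochs"), "`epochs` must be an eeg_epochs object")
  stop_if_not(threshold_uv > 0, "`threshold_uv` must be positive")
  peaks <- vapply(epochs$epochs, function(e) max(abs(e)), numeric(1))
  bad <- which(peaks > threshold_uv)
  chan <- vapply(bad, function(i) {
    e <- abs(epochs$epochs[[i]])
    epochs$labels[which(e == max(e), arr.ind = TRUE)[1, 1]]
  }, character(1))
  out <- epochs
  out$epochs <- epochs$epochs[setdiff(seq_along(epochs$epochs), bad)]
  attr(out, "report") <- data.frame(epoch = bad, channel = chan,
                                    max_abs_uv = peaks[bad])
  out
}

#' Trim epoch edges into analysis segments
#'
#' Drops `trim` seconds from both ends of every epoch, yielding the 2.5-s
#' analysis segments when applied to 3.5-s epochs with the default 0.5-s
#' trim.
#'
#' @param epochs An `eeg_epochs` object (typically band-filtered).
#' @param trim Seconds to discard from each edge (default 0.5).
#' @return A `segment_set`: list of channels x samples matrices plus band,
#'   condition, fs, labels and source-epoch provenance.
#' @export
trim_to_segments <- function(epochs, trim = 0.5) {
  stop_if_not(inherits(epochs, "eeg_epochs"), "`epochs` must be an eeg_epochs object")
  k <- round(trim * epochs$fs)
  segs <- lapply(epochs$epochs, function(e) {
    stop_if_not(ncol(e) > 2 * k, "epoch too short for the requested trim")
    if (k == 0) e else e[, (k + 1):(ncol(e) - k), drop = FALSE]
  })
  structure(list(segments = segs, fs = epochs$fs, labels = epochs$labels,
                 band = epochs$band, condition = epochs$condition,
                 provenance = seq_along(epochs$epochs)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  ns <- if (length(x$segments)) ncol(x$segments[[1]]) else 0
  cat(sprintf("<segment_set> %d segments, %d channels x %d samples @ %g Hz (band %s, condition %s)\n",
              length(x$segments), length(x$labels), ns, x$fs,
              x$band %||% "?", x$condition %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
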