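pad_field <- function(x, width) {
  x <- as.character(x)
  stop_if_not(nchar(x) <= width, sprintf("EDF field too long: '%s'", x))
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to European Data Format (EDF)
#'
#' Minimal 16-bit EDF writer: one 1-second data record per full second of
#' signal (a trailing partial second is dropped), symmetric physical range
#' per channel, digital range -32767..32767. The sampling rate must be a
#' whole number of samples per second.
#'
#' @param recording An [eeg_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stop_if_not(inherits(recording, "eeg_recording"), "`recording` must be an eeg_recording")
  fs <- recording$fs
  stop_if_not(fs == round(fs), "EDF writer requires an integer sampling rate")
  data <- recording$data
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  stop_if_not(n_rec >= 1, "recording shorter than one EDF record (1 s)")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- apply(abs(data), 1, max)
  pmax_[pmax_ == 0] <- 1
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wf("0", 8)
  wf("synthetic subject", 80)
  wf(sprintf("plinet simulated recording%s",
             if (is.na(recording$condition)) "" else paste0(" ", recording$condition)), 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256 * (1 + ns), 8)
  wf("", 44)
  wf(n_rec, 8)
  wf("1", 8)
  wf(ns, 4)
  for (l in recording$labels) wf(l, 16)
  for (i in seq_len(ns)) wf("simulated", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  # densest representation fitting the 8-char field: a coarse physical
  # range would corrupt the amplitude scaling on read-back
  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent physical range in an EDF field", call. = FALSE)
  }
  for (i in seq_len(ns)) wf(fmt8(-pmax_[i]), 8)
  for (i in seq_len(ns)) wf(fmt8(pmax_[i]), 8)
  for (i in seq_len(ns)) wf(-dmax, 8)
  for (i in seq_len(ns)) wf(dmax, 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(fs, 8)
  for (i in seq_len(ns)) wf("", 32)
  scale <- dmax / pmax_
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(data[i, idx] * scale[i]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for 16-bit EDF files as produced by [write_edf()] (and
#' standard single-rate EDF exports): all channels must share one sampling
#' rate.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep.
#' @param condition Optional condition tag for the returned recording.
#' @return An [eeg_recording] in physical units.
#' @export
read_edf <- function(path, channels = NULL, condition = NA_character_) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rf(8)
  stop_if_not(version == "0", sprintf("malformed EDF header: version field '%s'", version))
  rf(80); rf(80); rf(8); rf(8)
  header_bytes <- as.integer(rf(8))
  rf(44)
  n_rec <- as.integer(rf(8))
  rec_dur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  stop_if_not(is.finite(ns) && ns >= 1, "malformed EDF header: number-of-signals field")
  labels <- vapply(seq_len(ns), function(i) rf(16), character(1))
  for (i in seq_len(ns)) rf(80)
  for (i in seq_len(ns)) rf(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rf(8), character(1)))
  for (i in seq_len(ns)) rf(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rf(8), character(1)))
  for (i in seq_len(ns)) rf(32)
  stop_if_not(length(unique(spr)) == 1,
              "malformed EDF header: channels disagree on samples-per-record")
  stop_if_not(header_bytes == 256 * (1 + ns), "malformed EDF header: header-bytes field")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  rec <- eeg_recording(data, fs, labels, condition)
  if (!is.null(channels)) {
    stop_if_not(all(channels %in% labels), "requested channel label not in file")
    rec <- eeg_recording(rec$data[channels, , drop = FALSE], fs, channels, condition)
  }
  rec
}

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      kv[[paste(section, substr(ln, 1, eq - 1), sep = ".")]] <-
        substr(ln, eq + 1, nchar(ln))
    }
  }
  kv
}

#' Read a BrainVision recording (.vhdr + binary .eeg)
#'
#' Supports the common binary layout: multiplexed or vectorized
#' IEEE_FLOAT_32 or INT_16 data with per-channel resolution scaling.
#'
#' @param path Path to the `.vhdr` header file.
#' @param channels Optional labels to keep.
#' @param condition Optional condition tag.
#' @return An [eeg_recording] in physical units (resolution applied).
#' @export
read_brainvision <- function(path, channels = NULL, condition = NA_character_) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  kv <- parse_vhdr(path)
  need <- function(key) {
    v <- kv[[key]]
    stop_if_not(!is.null(v), sprintf("malformed BrainVision header: missing %s", key))
    v
  }
  stop_if_not(toupper(need("Common Infos.DataFormat")) == "BINARY",
              "malformed BrainVision header: only BINARY DataFormat supported")
  orient <- toupper(need("Common Infos.DataOrientation"))
  nch <- as.integer(need("Common Infos.NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("Common Infos.SamplingInterval"))
  fmt <- toupper(need("Binary Infos.BinaryFormat"))
  datafile <- file.path(dirname(path), need("Common Infos.DataFile"))
  stop_if_not(file.exists(datafile), sprintf("data file not found: %s", datafile))
  labels <- character(nch)
  res <- rep(1, nch)
  for (i in seq_len(nch)) {
    ch <- need(sprintf("Channel Infos.Ch%d", i))
    parts <- strsplit(ch, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  sz <- file.info(datafile)$size
  if (fmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw <- readBin(datafile, "numeric", n = n, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    n <- sz / 2
    raw <- readBin(datafile, "integer", n = n, size = 2, endian = "little")
  } else stop(sprintf("unsupported BinaryFormat: %s", fmt), call. = FALSE)
  nsamp <- floor(length(raw) / nch)
  raw <- raw[seq_len(nsamp * nch)]
  data <- if (orient == "MULTIPLEXED") matrix(raw, nrow = nch)
          else t(matrix(raw, ncol = nch))
  data <- data * res
  rec <- eeg_recording(data, fs, labels, condition)
  if (!is.null(channels)) {
    stop_if_not(all(channels %in% labels), "requested channel label not in file")
    rec <- eeg_recording(rec$data[channels, , drop = FALSE], fs, channels, condition)
  }
  rec
}

# test/support writer for the BrainVision reader (multiplexed float32)
write_brainvision <- function(recording, basepath) {
  vhdr <- paste0(basepath, ".vhdr")
  eeg <- paste0(basepath, ".eeg")
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           sprintf("DataFile=%s", basename(eeg)),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           sprintf("NumberOfChannels=%d", nrow(recording$data)),
           sprintf("SamplingInterval=%g", 1e6 / recording$fs),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_along(recording$labels), recording$labels))
  writeLines(hdr, vhdr)
  writeBin(as.numeric(recording$data), eeg, size = 4, endian = "little")
  invisible(vhdr)
}

#' Write a recording as a TSV matrix with a JSON sidecar
#'
#' Samples in rows, channels in columns with a header of labels; sampling
#' rate and condition go to `<path>.json`.
#'
#' @param recording An [eeg_recording].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(recording, path) {
  m <- t(recording$data)
  colnames(m) <- recording$labels
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs = recording$fs, condition = recording$condition),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multichannel recording from any supported format
#'
#' Dispatches on `format` (or the file extension for `"auto"`): `.edf` to
#' the EDF reader, `.vhdr` to the BrainVision reader, anything else to the
#' TSV reader (header row of channel labels; `fs` from the `.json` sidecar
#' or the `fs` argument).
#'
#' @param path Input file.
#' @param format `"auto"`, `"tsv"`, `"edf"` or `"brainvision"`.
#' @param fs Sampling rate override (required for TSV without sidecar).
#' @param channels Optional labels to keep.
#' @param condition Optional condition tag.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "tsv", "edf", "brainvision"),
                     fs = NULL, channels = NULL, condition = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", "tsv")
  }
  if (format == "edf") return(read_edf(path, channels, condition))
  if (format == "brainvision") return(read_brainvision(path, channels, condition))
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  m <- as.matrix(read.delim(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  if (is.null(fs) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    fs <- meta$fs
    if (is.na(condition) && !is.null(meta$condition) && !is.na(meta$condition))
      condition <- meta$condition
  }
  stop_if_not(!is.null(fs), "sampling rate unknown: supply `fs` or a .json sidecar")
  rec <- eeg_recording(t(m), fs, colnames(m), condition)
  if (!is.null(channels)) {
    stop_if_not(all(channels %in% rec$labels), "requested channel label not in file")
    rec <- eeg_recording(rec$data[channels, , drop = FALSE], fs, channels, condition)
  }
  rec
}

#' Write a PLI (or weight) matrix as labelled TSV
#' @param matrix Square labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  m <- as.data.frame(unclass(matrix))
  write.table(cbind(label = rownames(matrix), m), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#' @param path TSV written by [write_matrix_tsv()].
#' @param class Class to prepend to the result (default `pli_matrix`).
#' @return Labelled square matrix.
#' @export
read_matrix_tsv <- function(path, class = "pli_matrix") {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c(class, "matrix"))
}

#' Write a segment set to HDF5 (optional)
#'
#' Stores the segments as a channels x samples x segments array with band,
#' condition and sampling-rate attributes. Requires the `rhdf5` package;
#' errors if it is not installed (all core outputs are TSV, HDF5 is a
#' convenience sink).
#'
#' @param segments A `segment_set`.
#' @param path Output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_segments_h5 <- function(segments, path) {
  stop_if_not(requireNamespace("rhdf5", quietly = TRUE),
              "write_segments_h5 requires the rhdf5 package")
  if (file.exists(path)) file.remove(path)
  arr <- simplify2array(segments$segments)
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "segments")
  rhdf5::h5write(segments$labels, path, "labels")
  rhdf5::h5write(segments$fs, path, "fs")
  rhdf5::h5write(segments$band %||% "", path, "band")
  rhdf5::h5write(segments$condition %||% "", path, "condition")
  rhdf5::h5closeAll()
  invisible(path)
}
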