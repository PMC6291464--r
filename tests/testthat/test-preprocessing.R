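test_that("zero-phase band-pass meets its passband/stopband contract", {
  th <- default_bands()$theta
  mid <- 500:1250  # away from segment edges

  f6 <- bandpass_filter(tone_recording(6), th)
  expect_lt(abs(max(abs(f6$data[1, mid])) - 1), 0.10)

  # passband gain within +/-1 dB at the band centre frequency
  fc <- sqrt(4 * 8)
  fcr <- bandpass_filter(tone_recording(fc), th)
  gain_db <- 20 * log10(max(abs(fcr$data[1, mid])))
  expect_lt(abs(gain_db), 1)

  # one octave above the upper edge: >= 30 dB down after the double pass
  f20 <- bandpass_filter(tone_recording(20), th)
  expect_lt(20 * log10(max(abs(f20$data[1, mid]))), -30)

  expect_error(bandpass_filter(tone_recording(6, fs = 100),
                               band_definition("fast", 30, 60)), "Nyquist")
})

test_that("filtering is zero phase: cross-correlation peaks at lag 0", {
  rec <- tone_recording(6)
  f <- bandpass_filter(rec, default_bands()$theta)
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    idx <- 600:1200
    cor(rec$data[1, idx], f$data[1, idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("epoching cuts at the nearest sample and skips out-of-range onsets", {
  fs <- 500
  n <- 120
  dur <- 0.5 + 5 * n + 3.5
  rec <- eeg_recording(matrix(rnorm(2 * dur * fs), 2), fs, c("a", "b"))
  onsets <- 0.5 + 5 * (seq_len(n) - 1)
  eps <- extract_epochs(rec, onsets)
  expect_length(eps$epochs, 120)
  expect_equal(ncol(eps$epochs[[1]]), 1750)

  expect_length(extract_epochs(rec, numeric(0))$epochs, 0)

  # an onset 1 s before the end cannot host a 3.5-s epoch
  onsets_bad <- c(onsets[-n], dur - 1)
  expect_warning(eps2 <- extract_epochs(rec, onsets_bad), "skipped")
  expect_length(eps2$epochs, 119)
  expect_equal(eps2$skipped, 120L)
})

test_that("artifact rejection removes epochs strictly above threshold", {
  fs <- 250
  mk <- function(peak) {
    e <- matrix(rnorm(2 * 875, 0, 5), 2)
    e[1, 100] <- peak
    e
  }
  eps <- structure(list(epochs = c(list(mk(59.9), mk(61)),
                                   lapply(1:8, function(i) mk(30))),
                        fs = fs, labels = c("a", "b"),
                        condition = NA_character_, band = NULL,
                        skipped = integer(0)),
                   class = "eeg_epochs")
  # plant spikes into three of the quiet epochs
  eps$epochs[[4]][2, 5] <- -200
  eps$epochs[[6]][1, 9] <- 90
  eps$epochs[[9]][2, 1] <- 1000
  kept <- reject_artifacts(eps)
  rep <- attr(kept, "report")
  expect_length(kept$epochs, 6)          # 10 - (61 peak) - 3 spikes
  expect_true(all(c(2, 4, 6, 9) %in% rep$epoch))
  expect_equal(rep$channel[rep$epoch == 4], "b")

  # 59.9 peak is retained; rejection is idempotent
  expect_false(1 %in% rep$epoch)
  again <- reject_artifacts(kept)
  expect_length(again$epochs, 6)
  expect_equal(nrow(attr(again, "report")), 0)
})

test_that("trimming yields 2.5-s segments and rest slicing counts pseudo-epochs", {
  fs <- 500
  rec <- eeg_recording(matrix(rnorm(2 * 1750 * 3), 2), fs, c("a", "b"))
  eps <- extract_epochs(rec, c(0, 3.5, 7))
  segs <- trim_to_segments(eps)
  expect_equal(ncol(segs$segments[[1]]), 1250)
  expect_equal(segs$labels, c("a", "b"))

  segs0 <- trim_to_segments(eps, trim = 0)
  expect_identical(segs0$segments[[1]], eps$epochs[[1]])

  rest <- eeg_recording(matrix(0, 1, 300 * fs), fs, "z")
  expect_length(rest_onsets(rest), 85)   # floor(300 / 3.5)

  short <- extract_epochs(rec, 0, epoch_len = 0.9)
  expect_error(trim_to_segments(short, trim = 0.5), "too short")
})

test_that("filter-then-trim and trim-then-filter agree within edge tolerance", {
  th <- default_bands()$theta
  rec <- generate_recording(2, 3.5, 500, specs = list(
    coupling_spec(th, data.frame(i = 1, j = 2, target_pli = 1, lag_angle = 1), 6)),
    seed = 4, noise_sd = 2)
  eps <- extract_epochs(rec, 0)
  default_path <- trim_to_segments(bandpass_filter(eps, th))$segments[[1]]
  swapped <- bandpass_filter(
    eeg_recording(trim_to_segments(eps)$segments[[1]], 500, rec$labels), th)$data
  mid <- 300:950
  expect_gt(cor(default_path[1, mid], swapped[1, mid]), 0.99)
})

test_that("channel labels survive every preprocessing stage", {
  rec <- generate_recording(5, 8, 250, seed = 6)
  f <- bandpass_filter(rec, default_bands()$alpha)
  eps <- extract_epochs(f, rest_onsets(f))
  kept <- reject_artifacts(eps, threshold_uv = 1e6)
  segs <- trim_to_segments(kept)
  expect_equal(segs$labels, rec$labels)
  expect_equal(rownames(segs$segments[[1]]), rec$labels)
})
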