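# Independent oracles and fixture builders shared across test files.

# Brute-force Onnela clustering: explicit triple loop over triangles.
clustering_oracle <- function(W, denominator = "degree") {
  n <- nrow(W)
  C <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      num <- num + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    den <- if (denominator == "degree") {
      k <- sum(W[i, ] > 0)
      k * (k - 1)
    } else {
      s <- sum(W[i, ])
      s * (s - 1)
    }
    C[i] <- if (den > 0) num / den else 0
  }
  C
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/weight.
path_length_oracle <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  mean(D[row(D) != col(D)])
}

# Random complete symmetric weight matrix in (0, 1].
random_net <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.05, 1)
  W + t(W)
}

# Pure tone as a single-channel recording.
tone_recording <- function(freq, fs = 500, duration = 3.5, phase = 0, amp = 1) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  eeg_recording(matrix(amp * cos(2 * pi * freq * t + phase), 1), fs, "tone")
}

# Pooled-sign PLI estimate for a coupled pair over whole filtered recordings:
# the calibration estimator matching the generator's closed form |2q - 1|.
pooled_pair_pli <- function(recording, band, i, j) {
  f <- bandpass_filter(recording, band)
  ph <- analytic_phase(f$data)$phases
  pli_pair(ph[i, ], ph[j, ])
}
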