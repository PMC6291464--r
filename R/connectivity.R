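#' Instantaneous phase via the Hilbert analytic signal
#'
#' For each channel s(t) the analytic signal z(t) = s(t) + i*H[s](t) is
#' computed in the frequency domain (positive frequencies doubled, negative
#' zeroed); the instantaneous phase is its argument, wrapped to (-pi, pi].
#'
#' @param segment Numeric channels x samples matrix (a single analysis
#'   segment), all values finite, at least 2 samples.
#' @return An `analytic_phase` object: `phases` (channels x samples matrix,
#'   radians) with the source dimensions preserved.
#' @export
analytic_phase <- function(segment) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  stop_if_not(is.matrix(segment) && is.numeric(segment), "segment must be a numeric matrix")
  stop_if_not(all(is.finite(segment)), "segment contains non-finite values")
  n <- ncol(segment)
  stop_if_not(n >= 2, "segment must have at least 2 samples")
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(segment)) * mult
  z <- mvfft(X, inverse = TRUE) / n
  phases <- t(Arg(z))
  dimnames(phases) <- dimnames(segment)
  structure(list(phases = phases), class = "analytic_phase")
}

#' Phase lag index of one channel pair
#'
#' PLI = | < sign(sin(phi_a - phi_b)) > |, the absolute time-average of the
#' sign of the sine of the instantaneous phase difference. Ranges in
#' \[0, 1\]: 0 means no consistent non-zero-lag phase relation (identical
#' signals give exactly 0 under the sign(0) = 0 convention), 1 means a
#' perfectly consistent non-zero lag. Insensitive to zero-lag (common
#' source / volume conduction) coupling.
#'
#' @param phase_a,phase_b Numeric phase vectors of equal length (radians).
#' @param tol Magnitudes of sin(dphi) at or below this are treated as the
#'   exact zero of the sign(0) = 0 convention (default 1e-9), so channels
#'   identical up to positive scaling give PLI 0 despite FFT roundoff;
#'   genuine phase differences are orders of magnitude larger.
#' @return Scalar PLI in \[0, 1\].
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 500)
#' pli_pair(2 * pi * 6 * t, 2 * pi * 6 * t - pi / 4)  # constant lag: 1
pli_pair <- function(phase_a, phase_b, tol = 1e-9) {
  stop_if_not(length(phase_a) == length(phase_b), "phase vectors differ in length")
  stop_if_not(length(phase_a) >= 1, "empty phase vectors")
  s <- sin(phase_a - phase_b)
  s[abs(s) <= tol] <- 0
  abs(mean(sign(s)))
}

#' PLI connectivity matrix over all channel pairs
#'
#' @param phases An `analytic_phase` object (or a channels x samples phase
#'   matrix) with at least 2 channels.
#' @return A `pli_matrix`: symmetric n x n matrix, zero diagonal, entries
#'   in \[0, 1\], channel labels as dimnames.
#' @export
pli_matrix <- function(phases) {
  P <- if (inherits(phases, "analytic_phase")) phases$phases else phases
  stop_if_not(is.matrix(P), "phases must be a matrix or analytic_phase")
  n <- nrow(P)
  stop_if_not(n >= 2, "at least 2 channels required")
  out <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1)) {
    d <- sin(sweep(P[(i + 1):n, , drop = FALSE], 2, P[i, ], "-"))
    d[abs(d) <= 1e-9] <- 0
    v <- abs(rowMeans(sign(d)))
    out[i, (i + 1):n] <- v
    out[(i + 1):n, i] <- v
  }
  structure(out, class = c("pli_matrix", "matrix"))
}

#' Global synchronization: mean PLI over all node pairs
#'
#' Mean of the n(n-1)/2 upper-triangle entries (diagonal excluded).
#'
#' @param matrix A `pli_matrix` (or any symmetric matrix).
#' @return Scalar mean PLI.
#' @export
average_pli <- function(matrix) {
  stop_if_not(nrow(matrix) >= 2, "matrix must have at least 2 nodes")
  mean(matrix[upper.tri(matrix)])
}

#' Entrywise average of per-segment PLI matrices
#'
#' Collapses the per-segment matrices of one condition into a single
#' condition-level matrix. Downstream metrics are computed per segment and
#' then averaged by default (see [condition_metrics()]); this entrywise
#' average is the alternative, switchable path.
#'
#' @param matrices Non-empty list of shape-consistent `pli_matrix` objects.
#' @return A `pli_matrix` of entrywise means.
#' @export
condition_average <- function(matrices) {
  stop_if_not(is.list(matrices) && length(matrices) >= 1, "need a non-empty list of matrices")
  d <- dim(matrices[[1]])
  stop_if_not(all(vapply(matrices, function(m) identical(dim(m), d), logical(1))),
              "matrices differ in shape")
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(out, class = c("pli_matrix", "matrix"))
}

#' PLI matrices for every segment of a segment set
#'
#' @param segments A `segment_set` from [trim_to_segments()].
#' @return List of `pli_matrix`, one per segment.
#' @export
segment_pli <- function(segments) {
  stop_if_not(inherits(segments, "segment_set"), "`segments` must be a segment_set")
  lapply(segments$segments, function(s) pli_matrix(analytic_phase(s)))
}
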