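#' Build a weighted undirected network from a PLI matrix
#'
#' The network is fully connected in principle: weights are copied verbatim
#' from the connectivity matrix with no thresholding and no binarization
#' (threshold choice would otherwise become an uncontrolled analysis knob).
#'
#' @param matrix Symmetric nonnegative matrix with zero diagonal
#'   (typically a `pli_matrix`).
#' @return A `weighted_network`: the weight matrix with labels.
#' @export
build_network <- function(matrix) {
  m <- unclass(matrix)
  stop_if_not(is.matrix(m) && nrow(m) == ncol(m), "input must be square")
  stop_if_not(isTRUE(all.equal(m, t(m))), "input must be symmetric")
  stop_if_not(all(diag(m) == 0), "diagonal must be zero")
  stop_if_not(all(m >= 0), "weights must be nonnegative")
  structure(m, class = c("weighted_network", "matrix"))
}

#' Weighted clustering coefficient per node (Onnela)
#'
#' C_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1)), the intensity
#' of closed triangles around node i using geometric-mean edge weights.
#' Weights are assumed already in \[0, 1\] (PLI), so no max-weight
#' renormalization is applied. `denominator = "strength"` switches to the
#' strength-based normalization s_i (s_i - 1), which is degenerate for
#' node strengths at or below 1 and is provided for comparison only.
#'
#' @param net A `weighted_network` with at least 3 nodes.
#' @param denominator `"degree"` (default, k_i(k_i - 1) with k_i the number
#'   of nonzero-weight neighbours) or `"strength"`.
#' @return Named numeric vector of nodal clustering values; nodes with
#'   fewer than 2 neighbours get 0.
#' @export
nodal_clustering <- function(net, denominator = c("degree", "strength")) {
  denominator <- match.arg(denominator)
  W <- unclass(net)
  stop_if_not(nrow(W) >= 3, "clustering requires at least 3 nodes")
  W3 <- W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  if (denominator == "degree") {
    k <- rowSums(W > 0)
    den <- k * (k - 1)
    C <- ifelse(k < 2, 0, num / den)
  } else {
    s <- rowSums(W)
    den <- s * (s - 1)
    C <- ifelse(den <= 0, NaN, num / den)
  }
  names(C) <- rownames(W)
  C
}

#' Global clustering coefficient
#'
#' Arithmetic mean of the nodal clustering coefficients (functional
#' segregation index).
#'
#' @inheritParams nodal_clustering
#' @return Scalar global clustering.
#' @export
global_clustering <- function(net, denominator = c("degree", "strength")) {
  mean(nodal_clustering(net, denominator))
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered node pairs, with edge length the
#' inverse of the weight (weight 0 means no edge). Functional integration
#' index.
#'
#' @param net A `weighted_network`.
#' @param disconnected `"error"` (default; a PLI-derived network is fully
#'   connected whenever weights are positive) or `"reachable"` to average
#'   over reachable pairs only.
#' @return Scalar characteristic path length.
#' @export
char_path_length <- function(net, disconnected = c("error", "reachable")) {
  disconnected <- match.arg(disconnected)
  W <- unclass(net)
  n <- nrow(W)
  stop_if_not(n >= 2, "path length requires at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off))) {
    if (disconnected == "error") stop("network is disconnected", call. = FALSE)
    off <- off[is.finite(off)]
    stop_if_not(length(off) > 0, "no reachable node pairs")
  }
  mean(off)
}

#' Weight-shuffled surrogate network
#'
#' Randomly permutes the multiset of upper-triangle weights across node
#' pairs, preserving symmetry, the zero diagonal and the complete topology.
#' Degree-preserving rewiring is vacuous on fully connected graphs, so
#' weight permutation is the null model used for small-world normalization.
#'
#' @param net A `weighted_network` with at least 3 nodes.
#' @param seed Integer seed (optional; uses the current RNG stream if NULL).
#' @return A `weighted_network` with identical sorted weight list.
#' @export
randomize_weights <- function(net, seed = NULL) {
  W <- unclass(net)
  n <- nrow(W)
  stop_if_not(n >= 3, "surrogates require at least 3 nodes")
  shuffle <- function() {
    ut <- upper.tri(W)
    out <- matrix(0, n, n, dimnames = dimnames(W))
    out[ut] <- sample(W[ut])
    out + t(out)
  }
  out <- if (is.null(seed)) shuffle() else with_seed(seed, shuffle())
  structure(out, class = c("weighted_network", "matrix"))
}

#' Small-world coefficient against weight-shuffled surrogates
#'
#' SW = (C / C_rand) / (L / L_rand), where C_rand and L_rand are means of
#' the global clustering and characteristic path length over an ensemble of
#' weight-shuffled surrogate networks. For weight-shuffled complete
#' weighted graphs SW is close to 1 by construction.
#'
#' @param net A `weighted_network`.
#' @param n_surrogates Number of surrogate networks (default 50).
#' @param seed Integer seed for the surrogate ensemble.
#' @param denominator Clustering normalization, see [nodal_clustering()].
#' @return A `network_metrics` list: `nodal_C`, `C`, `L`, `C_rand`,
#'   `L_rand`, `SW`, `n_surrogates`, `seed`.
#' @export
small_world <- function(net, n_surrogates = 50, seed = NULL,
                        denominator = c("degree", "strength")) {
  denominator <- match.arg(denominator)
  stop_if_not(n_surrogates >= 1, "need at least one surrogate")
  nodal_C <- nodal_clustering(net, denominator)
  C <- mean(nodal_C)
  L <- char_path_length(net)
  run <- function() {
    Cs <- numeric(n_surrogates)
    Ls <- numeric(n_surrogates)
    for (b in seq_len(n_surrogates)) {
      for (attempt in 1:100) {
        sur <- randomize_weights(net)
        Lb <- tryCatch(char_path_length(sur), error = function(e) NULL)
        if (!is.null(Lb)) break
      }
      stop_if_not(!is.null(Lb), "could not draw a connected surrogate")
      Cs[b] <- global_clustering(sur, denominator)
      Ls[b] <- Lb
    }
    list(C_rand = mean(Cs), L_rand = mean(Ls))
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(nodal_C = nodal_C, C = C, L = L,
                 C_rand = r$C_rand, L_rand = r$L_rand,
                 SW = (C / r$C_rand) / (L / r$L_rand),
                 n_surrogates = n_surrogates, seed = seed),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> C = %.4f  L = %.4f  C_rand = %.4f  L_rand = %.4f  SW = %.4f (%d surrogates)\n",
              x$C, x$L, x$C_rand, x$L_rand, x$SW, x$n_surrogates))
  invisible(x)
}

#' Condition-level network metrics from per-segment PLI matrices
#'
#' The default path computes every metric per segment and averages the
#' results across segments (nodal and global clustering, path length, and
#' small-world coefficient); `path = "average"` instead averages the PLI
#' matrices entrywise first and computes the metrics once on the mean
#' matrix.
#'
#' @param matrices List of per-segment `pli_matrix` objects.
#' @param n_surrogates Surrogates per small-world evaluation (default 50).
#' @param seed Integer seed.
#' @param path `"per-segment"` (default) or `"average"`.
#' @param denominator Clustering normalization, see [nodal_clustering()].
#' @return A `network_metrics` list (averaged over segments for the
#'   per-segment path), plus `avg_pli`, the mean over segments of the
#'   global average PLI.
#' @export
condition_metrics <- function(matrices, n_surrogates = 50, seed = NULL,
                              path = c("per-segment", "average"),
                              denominator = c("degree", "strength")) {
  path <- match.arg(path)
  denominator <- match.arg(denominator)
  stop_if_not(length(matrices) >= 1, "need at least one segment matrix")
  if (path == "average") {
    net <- build_network(condition_average(matrices))
    m <- small_world(net, n_surrogates, seed, denominator)
    m$avg_pli <- average_pli(condition_average(matrices))
    return(m)
  }
  per <- lapply(seq_along(matrices), function(i) {
    net <- build_network(matrices[[i]])
    m <- small_world(net, n_surrogates,
                     if (is.null(seed)) NULL else derive_seed(seed, i),
                     denominator)
    m$avg_pli <- average_pli(matrices[[i]])
    m
  })
  agg <- function(f) mean(vapply(per, f, numeric(1)))
  structure(list(
    nodal_C = rowMeans(vapply(per, function(m) m$nodal_C,
                              numeric(length(per[[1]]$nodal_C)))),
    C = agg(function(m) m$C), L = agg(function(m) m$L),
    C_rand = agg(function(m) m$C_rand), L_rand = agg(function(m) m$L_rand),
    SW = agg(function(m) m$SW), avg_pli = agg(function(m) m$avg_pli),
    n_surrogates = n_surrogates, seed = seed, n_segments = length(per)),
    class = "network_metrics")
}
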