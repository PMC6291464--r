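stat_result <- function(test, statistic, p_raw, direction = NA_real_,
                        method = NA_character_, p_adjusted = NA_real_,
                        family = NA_character_, extra = NULL) {
  structure(c(list(test = test, statistic = statistic, p_raw = p_raw,
                   p_adjusted = p_adjusted, direction = direction,
                   method = method, family = family), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g%s%s\n", x$test, x$statistic,
              x$p_raw,
              if (!is.na(x$p_adjusted)) sprintf(", p.adj = %.4g", x$p_adjusted) else "",
              if (!is.na(x$direction)) sprintf(", direction = %+d", sign(x$direction)) else ""))
  invisible(x)
}

#' Partial correlation with covariate control
#'
#' Rank-based by default (all variables rank-transformed before
#' residualization, matching a nonparametric analysis battery): x and y are
#' residualized on the covariates by least squares and the residuals are
#' correlated; the p-value uses the t approximation with
#' df = n - 2 - n_covariates. `method = "linear"` skips the rank transform.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @param method `"rank"` (default) or `"linear"`.
#' @return A `stat_result` with the partial correlation as `statistic`.
#' @export
partial_correlation <- function(x, y, covariates, method = c("rank", "linear")) {
  method <- match.arg(method)
  Z <- as.matrix(covariates)
  stop_if_not(length(x) == length(y) && nrow(Z) == length(x),
              "x, y and covariates must have matching length")
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  stop_if_not(n >= k + 4, "too few complete cases for partial correlation")
  if (method == "rank") {
    x <- rank(x); y <- rank(y)
    Z <- apply(Z, 2, rank)
  }
  Zi <- cbind(1, Z)
  stop_if_not(qr(Zi)$rank == ncol(Zi), "covariates are collinear")
  ex <- x - Zi %*% qr.solve(Zi, x)
  ey <- y - Zi %*% qr.solve(Zi, y)
  stop_if_not(sd(ex) > 1e-8 * sd(x) && sd(ey) > 1e-8 * sd(y),
              "a covariate is collinear with x or y")
  r <- cor(ex, ey)[1, 1]
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  stat_result("partial_correlation", r, min(p, 1), direction = sign(r),
              method = method, extra = list(df = df, n = n, t = tval))
}

# within-subject mid-ranks for a subjects x k matrix
row_ranks <- function(values) t(apply(values, 1, rank))

#' Friedman test for k repeated conditions
#'
#' Chi-square statistic on within-subject mid-ranks with the standard tie
#' correction; p from the chi-square distribution with k - 1 df. Requires a
#' complete block design (no missing cells).
#'
#' @param values Numeric subjects x conditions matrix (k >= 2 columns,
#'   n >= 2 rows).
#' @return A `stat_result`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  stop_if_not(all(is.finite(values)), "missing cells: Friedman needs complete blocks")
  n <- nrow(values); k <- ncol(values)
  stop_if_not(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 conditions")
  R <- row_ranks(values)
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction: per-subject tie multiset
  ties <- sum(apply(values, 1, function(v) {
    t <- table(v); sum(t^3 - t)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr > 0) stat <- stat / corr
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  stat_result("friedman", stat, p, extra = list(df = k - 1, n = n, k = k,
                                                rank_sums = Rj))
}

#' Post-hoc pairwise comparisons after a Friedman test
#'
#' Default adjustment is the studentized-range procedure on Friedman rank
#' sums (Nemenyi-type, the standard "Tukey-Kramer style" follow-up for a
#' repeated-measures rank design): for each pair,
#' q = |mean rank difference| / sqrt(k(k+1) / (6n)) compared against the
#' studentized range distribution. Plain paired Wilcoxon signed-rank
#' p-values are co-reported for every pair.
#'
#' @param values Numeric subjects x conditions matrix.
#' @param method `"wsr_adjusted"` (default; WSR statistics with
#'   studentized-range adjusted p from the rank sums) or `"nemenyi"`.
#' @return List of `stat_result`, one per condition pair; each carries the
#'   adjusted p (`p_adjusted`) and the plain WSR p (`p_raw`).
#' @export
posthoc_pairwise <- function(values, method = c("wsr_adjusted", "nemenyi")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stop_if_not(k >= 2, "need at least 2 conditions")
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  Rbar <- colMeans(row_ranks(values))
  se <- sqrt(k * (k + 1) / (6 * n))
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    q <- abs(Rbar[i] - Rbar[j]) / se
    w <- wilcoxon_signed_rank(values[, i], values[, j])
    p_adj <- if (k == 2) {
      w$p_raw   # single comparison: adjustment is the identity
    } else {
      ptukey(q * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    }
    out[[paste(cn[i], cn[j], sep = " vs ")]] <-
      stat_result("posthoc_pairwise",
                  statistic = if (method == "nemenyi") q else w$statistic,
                  p_raw = w$p_raw, p_adjusted = min(p_adj, 1),
                  direction = sign(Rbar[j] - Rbar[i]), method = method,
                  extra = list(pair = c(cn[i], cn[j]), q = q))
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided. Zero differences are dropped; exact p by enumeration of the
#' signed-rank null (no ties among nonzero |differences|, n <= 25),
#' otherwise the tie-corrected normal approximation. All differences zero
#' gives the degenerate p = 1.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @return A `stat_result` with the signed-rank sum W (of positive ranks)
#'   as `statistic` and the median-difference sign as `direction`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stop_if_not(length(paired_a) == length(paired_b), "paired vectors differ in length")
  d <- paired_a - paired_b
  d <- d[!is.na(d)]
  dir <- sign(median(d))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(stat_result("wilcoxon_signed_rank", 0, 1, direction = 0,
                       method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    p <- 2 * min(psignrank(W, n), psignrank(W - 1, n, lower.tail = FALSE))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    if (W == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  stat_result("wilcoxon_signed_rank", W, min(p, 1), direction = dir,
              method = method, extra = list(n = n))
}

#' Mann-Whitney U test (two independent samples)
#'
#' Two-sided. Exact p by enumeration of the U null when both groups have at
#' most 10 observations and there are no cross-sample ties; tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A `stat_result` with U (count of (a, b) pairs with a > b, plus
#'   half-ties) as `statistic`; direction is the sign of U - n1 n2 / 2
#'   (positive means `a` tends larger).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  stop_if_not(n1 >= 1 && n2 >= 1, "both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (!has_ties && n1 <= 10 && n2 <= 10) {
    p <- 2 * min(pwilcox(U, n1, n2), pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(c(a, b))
    N <- n1 + n2
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    if (U == mu) z <- 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  stat_result("mann_whitney_u", U, min(p, 1), direction = sign(U - n1 * n2 / 2),
              method = method, extra = list(n1 = n1, n2 = n2))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level q: rejects all ordered p(i) with
#' i <= max(i : p(i) <= i q / m); adjusted p-values by the standard
#' monotone min-cummin transform.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (one family).
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical mask in input order), `p_adjusted`,
#'   and `q`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)$reject
bh_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0) return(list(reject = logical(0), p_adjusted = numeric(0), q = q))
  stop_if_not(all(p_values >= 0 & p_values <= 1), "p-values must lie in [0, 1]")
  o <- order(p_values)
  ps <- p_values[o]
  thresh <- seq_len(m) * q / m
  below <- which(ps <= thresh)
  kmax <- if (length(below)) max(below) else 0
  reject <- logical(m)
  if (kmax > 0) reject[o[seq_len(kmax)]] <- TRUE
  adj <- rev(cummin(rev(pmin(ps * m / seq_len(m), 1))))
  p_adjusted <- numeric(m)
  p_adjusted[o] <- adj
  list(reject = reject, p_adjusted = p_adjusted, q = q)
}
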