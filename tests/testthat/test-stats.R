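test_that("partial correlation recovers exact and residualized relations", {
  set.seed(1)
  x <- rnorm(30)
  z <- rnorm(30)
  r1 <- partial_correlation(x, x, z)
  expect_equal(r1$statistic, 1)

  # covariate orthogonal to both (constructed): partial equals zero-order
  y <- rnorm(30)
  zz <- rnorm(30)
  zo <- resid(lm(zz ~ x + y))
  rl <- partial_correlation(x, y, zo, method = "linear")
  expect_equal(rl$statistic, cor(resid(lm(x ~ zo)), resid(lm(y ~ zo))))
  expect_equal(rl$statistic, cor(x, y), tolerance = 1e-10)

  expect_error(partial_correlation(x, x, x), "collinear")
  expect_error(partial_correlation(1:3, 1:3, c(1, 2, 4)), "complete cases")

  # Monte-Carlo null: confound fully explained by the shared covariate
  hits <- vapply(1:100, function(r) {
    set.seed(900 + r)
    z <- rnorm(200)
    a <- z + rnorm(200)
    b <- z + rnorm(200)
    abs(partial_correlation(a, b, z)$statistic) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Friedman statistic matches closed forms and rank invariances", {
  same <- matrix(5, 4, 3)
  expect_equal(friedman_test(same)$statistic, 0)
  expect_equal(friedman_test(same)$p_raw, 1)

  inc <- matrix(rep(c(1, 2, 3), each = 5), 5)   # strictly increasing: 2n
  r <- friedman_test(inc)
  expect_equal(r$statistic, 10)
  expect_equal(r$p_raw, pchisq(10, 2, lower.tail = FALSE))

  set.seed(2)
  v <- matrix(rnorm(30), 10, 3)
  perm <- c(3, 1, 2)
  expect_equal(friedman_test(v[, perm])$statistic, friedman_test(v)$statistic)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2)), "complete blocks")
})

test_that("post-hoc pairwise comparisons control size and find real shifts", {
  set.seed(3)
  v2 <- matrix(rnorm(40), 20, 2)
  ph2 <- posthoc_pairwise(v2)
  expect_length(ph2, 1)
  expect_equal(ph2[[1]]$p_adjusted, ph2[[1]]$p_raw)  # k = 2: identity

  # power: one condition shifted by 3 SD
  hits <- vapply(1:100, function(r) {
    set.seed(400 + r)
    v <- cbind(rnorm(20), rnorm(20), rnorm(20, 3))
    colnames(v) <- c("a", "b", "c")
    ph <- posthoc_pairwise(v)
    ph[["a vs c"]]$p_adjusted < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)

  # family-wise error on all-null data
  fwe <- vapply(1:1000, function(r) {
    set.seed(7000 + r)
    v <- matrix(rnorm(60), 20, 3)
    any(vapply(posthoc_pairwise(v), function(x) x$p_adjusted < 0.05, logical(1)))
  }, logical(1))
  expect_lte(mean(fwe), 0.07)
})

test_that("Wilcoxon signed-rank matches enumeration and symmetry", {
  r <- wilcoxon_signed_rank(7:12, rep(0, 6))
  expect_equal(r$statistic, 21)
  expect_equal(r$p_raw, 2 / 64)     # all 6 differences positive
  expect_equal(r$method, "exact")

  a <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(a, a)$p_raw, 1)

  set.seed(4)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  expect_equal(wilcoxon_signed_rank(x, y)$p_raw, wilcoxon_signed_rank(y, x)$p_raw)
  expect_equal(wilcoxon_signed_rank(x, y)$direction,
               -wilcoxon_signed_rank(y, x)$direction)
})

test_that("Mann-Whitney U matches enumeration and symmetry", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 0.1)        # 2 / choose(6, 3)
  expect_equal(r$method, "exact")

  b <- c(1.5, 2.5, 3.5, 4.5)
  req <- mann_whitney_u(b, b)
  expect_equal(req$statistic, length(b)^2 / 2)
  expect_gt(req$p_raw, 0.9)

  set.seed(5)
  x <- rnorm(9); y <- rnorm(7, 1)
  expect_equal(mann_whitney_u(x, y)$p_raw, mann_whitney_u(y, x)$p_raw)
})

test_that("BH step-up matches hand-derived cases and the reference implementation", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(r$reject, rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.2, 0.5, 0.9), q = 0.05)$reject, rep(FALSE, 3))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  expect_equal(bh_fdr(numeric(0))$reject, logical(0))

  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(25)^2
    mine <- bh_fdr(p)
    expect_equal(mine$p_adjusted, p.adjust(p, method = "BH"))
    expect_true(all(mine$p_adjusted >= p - 1e-12))  # float slack in p * m / i
    expect_equal(mine$reject, mine$p_adjusted <= 0.05)
  }
})
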