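test_that("build_network copies weights verbatim and validates shape", {
  W <- random_net(5, 1)
  net <- build_network(W)
  expect_equal(unclass(net), W)
  W0 <- W; W0[1, 2] <- W0[2, 1] <- 0
  expect_silent(build_network(W0))
  bad <- W; bad[1, 2] <- 0.9
  expect_error(build_network(bad), "symmetric")
  expect_equal(nrow(build_network(random_net(59, 2))), 59)
})

test_that("clustering matches hand-derived cases", {
  W <- matrix(0.5, 3, 3); diag(W) <- 0
  expect_equal(unname(nodal_clustering(build_network(W))), rep(0.5, 3))

  # binary path a-b-c: no closed triangle anywhere
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  expect_equal(unname(nodal_clustering(build_network(P))), rep(0, 3))

  # star: hub's neighbours are unconnected, leaves have k = 1
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 0.8
  expect_equal(unname(nodal_clustering(build_network(S))), rep(0, 5))

  # uniform complete network: C = w (checked by brute force at n = 5)
  U <- matrix(0.3, 5, 5); diag(U) <- 0
  expect_equal(global_clustering(build_network(U)), 0.3)
  expect_equal(unname(nodal_clustering(build_network(U))),
               clustering_oracle(U), tolerance = 1e-12)

  Z <- matrix(0, 4, 4)
  expect_equal(global_clustering(build_network(Z)), 0)
  expect_error(nodal_clustering(build_network(matrix(0, 2, 2))), "at least 3")
})

test_that("path length matches hand-derived cases", {
  two <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(char_path_length(build_network(two)), 2)

  W <- matrix(0.5, 3, 3); diag(W) <- 0
  expect_equal(char_path_length(build_network(W)), 2)

  # indirect route beats the weak direct edge: d(a,c) = 4 via b
  V <- matrix(0, 3, 3)
  V[1, 2] <- V[2, 1] <- 0.5; V[2, 3] <- V[3, 2] <- 0.5; V[1, 3] <- V[3, 1] <- 0.1
  expect_equal(char_path_length(build_network(V)), 8 / 3)

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- 1; disc[3, 4] <- disc[4, 3] <- 1
  expect_error(char_path_length(build_network(disc)), "disconnected")
  expect_equal(char_path_length(build_network(disc), "reachable"), 1)
})

test_that("clustering and path length agree with brute-force oracles", {
  for (seed in 1:30) {
    W <- random_net(10, seed)
    # sprinkle some zero-weight (absent) edges
    if (seed %% 3 == 0) {
      set.seed(seed + 500)
      kill <- sample(which(upper.tri(W)), 5)
      W[kill] <- 0
      W[lower.tri(W)] <- t(W)[lower.tri(W)]
    }
    net <- build_network(W)
    expect_equal(unname(nodal_clustering(net)), clustering_oracle(W),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_clustering(net, "strength")),
                 clustering_oracle(W, "strength"), tolerance = 1e-10)
    L <- tryCatch(char_path_length(net), error = function(e) NA)
    if (!is.na(L)) expect_equal(L, path_length_oracle(W), tolerance = 1e-10)
  }
})

test_that("weight shuffling preserves the weight multiset and the seed contract", {
  U <- matrix(0.4, 6, 6); diag(U) <- 0
  expect_equal(unclass(randomize_weights(build_network(U), seed = 1)), U)

  W <- random_net(8, 3)
  net <- build_network(W)
  sur <- randomize_weights(net, seed = 5)
  expect_equal(sort(sur[upper.tri(sur)]), sort(W[upper.tri(W)]))
  expect_identical(unclass(randomize_weights(net, seed = 5)),
                   unclass(randomize_weights(net, seed = 5)))
  expect_equal(unname(diag(sur)), rep(0, 8))
  expect_identical(unclass(sur), t(unclass(sur)))
})

test_that("small-world coefficient behaves on uniform, scaled and relabeled nets", {
  U <- matrix(0.5, 6, 6); diag(U) <- 0
  m <- small_world(build_network(U), n_surrogates = 5, seed = 1)
  expect_identical(m$SW, 1)

  W <- random_net(12, 7)
  net <- build_network(W)
  m1 <- small_world(net, n_surrogates = 20, seed = 2)
  # global rescaling: C linear, L inverse, SW invariant
  m2 <- small_world(build_network(3 * W), n_surrogates = 20, seed = 2)
  expect_equal(m2$C, 3 * m1$C, tolerance = 1e-12)
  expect_equal(m2$L, m1$L / 3, tolerance = 1e-12)
  expect_equal(m2$SW, m1$SW, tolerance = 1e-10)

  # permutation equivariance
  p <- sample(12)
  mp <- small_world(build_network(W[p, p]), n_surrogates = 20, seed = 2)
  expect_equal(unname(mp$nodal_C), unname(m1$nodal_C[p]), tolerance = 1e-12)
  expect_equal(mp$C, m1$C, tolerance = 1e-12)
  expect_equal(mp$L, m1$L, tolerance = 1e-12)
})

test_that("condition_metrics averages per-segment metrics by default", {
  mats <- lapply(1:4, function(i) {
    m <- matrix(0, 5, 5)
    m[upper.tri(m)] <- runif(10, 0.1, 0.9)
    structure(m + t(m), class = c("pli_matrix", "matrix"))
  })
  cm <- condition_metrics(mats, n_surrogates = 5, seed = 3)
  per <- sapply(mats, function(m) global_clustering(build_network(m)))
  expect_equal(cm$C, mean(per))
  expect_equal(cm$avg_pli, mean(sapply(mats, average_pli)))
  cma <- condition_metrics(mats, n_surrogates = 5, seed = 3, path = "average")
  expect_equal(cma$C, global_clustering(build_network(condition_average(mats))))
})
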