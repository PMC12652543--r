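# Brute-force oracle for the graph-weighted alignment gram.
oracle_gram <- function(similarities, Q) {
  M <- length(similarities)
  n <- nrow(Q)
  G <- matrix(0, M, M)
  for (m in 1:M) for (mp in 1:M) {
    acc <- 0
    for (i in 1:n) for (j in 1:n) {
      di <- similarities[[m]][i, ] - similarities[[m]][j, ]
      dj <- similarities[[mp]][i, ] - similarities[[mp]][j, ]
      acc <- acc + Q[i, j] * sum(di * dj)
    }
    G[m, mp] <- acc
  }
  G
}

row_stochastic <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  A <- (A + t(A)) / 2
  R <- A / rowSums(A)
  (R + t(R)) / 2     # symmetric, rows ~1: like a composite similarity
}

test_that("the edge-frequency matrix counts kNN graph membership", {
  # chain 1-2-3-4: similarity decays with index distance
  S <- outer(1:4, 1:4, function(i, j) 1 / (1 + abs(i - j)))
  Q <- build_q(list(S), umkl_params(knn_k = 1))
  # brute-force 1-NN: each vertex picks its nearest other vertex
  A_expected <- matrix(0L, 4, 4)
  for (i in 1:4) {
    s <- S[i, ]; s[i] <- -Inf
    j <- which.max(s)
    A_expected[i, j] <- 1L
  }
  A_expected <- pmax(A_expected, t(A_expected))
  expect_equal(Q, A_expected)
  expect_true(all(diag(Q) == 0))
  # duplicated omics double the counts
  Q2 <- build_q(list(S, S), umkl_params(knn_k = 1))
  expect_equal(Q2, 2L * Q)
})

test_that("the alignment gram matches a triple-loop reference", {
  sims <- list(row_stochastic(4, 1), row_stochastic(4, 2))
  Q <- build_q(sims, umkl_params(knn_k = 2))
  expect_lt(max(abs(fusion_gram(sims, Q) - oracle_gram(sims, Q))), 1e-10)
  # identical similarities: all gram entries equal
  sims_same <- list(sims[[1]], sims[[1]], sims[[1]])
  G <- fusion_gram(sims_same, Q)
  expect_lt(diff(range(G)), 1e-10)
  # empty graph: zero gram
  expect_true(all(fusion_gram(sims, matrix(0, 4, 4)) == 0))
})

test_that("the simplex QP solution is exact (vertex and grid oracles)", {
  expect_equal(solve_beta(matrix(5, 1, 1)), 1)
  # exchange symmetry between omics 1 and 2
  G <- matrix(c(2, 1, 0.5,
                1, 2, 0.5,
                0.5, 0.5, 3), 3, 3)
  b <- solve_beta(G)
  expect_equal(b[1], b[2], tolerance = 1e-9)
  set.seed(3)
  for (i in 1:10) {
    A <- matrix(stats::rnorm(9), 3, 3)
    G <- crossprod(A) + 0.1 * diag(3)
    b <- solve_beta(G)
    expect_equal(sum(b), 1, tolerance = 1e-10)
    expect_true(all(b >= -1e-12))
    # exhaustive simplex grid at step 1e-3
    g1 <- seq(0, 1, by = 1e-3)
    best <- Inf; best_b <- NULL
    for (b1 in g1) {
      b2 <- seq(0, 1 - b1, by = 1e-3)
      b3 <- 1 - b1 - b2
      vals <- G[1, 1] * b1^2 + G[2, 2] * b2^2 + G[3, 3] * b3^2 +
        2 * G[1, 2] * b1 * b2 + 2 * G[1, 3] * b1 * b3 + 2 * G[2, 3] * b2 * b3
      k <- which.min(vals)
      if (vals[k] < best) { best <- vals[k]; best_b <- c(b1, b2[k], b3[k]) }
    }
    expect_equal(b, best_b, tolerance = 2e-3)
    # returned objective no worse than any vertex
    for (v in 1:3) expect_lte(drop(t(b) %*% G %*% b), G[v, v] + 1e-9)
  }
})

test_that("fusion is the advertised convex combination", {
  sims <- list(row_stochastic(5, 4), row_stochastic(5, 5),
               row_stochastic(5, 6))
  expect_identical(fuse(sims, c(1, 0, 0)), sims[[1]])
  expect_equal(fuse(list(sims[[1]], sims[[1]]), c(0.3, 0.7)), sims[[1]],
               tolerance = 1e-12)
  S_mean <- (sims[[1]] + sims[[2]] + sims[[3]]) / 3
  expect_lt(max(abs(fuse(sims, rep(1 / 3, 3)) - S_mean)), 1e-12)
  expect_error(fuse(sims, c(0.5, 0.5)), "length")
})

test_that("omic order does not change the fused kernel", {
  sims <- list(row_stochastic(12, 7), row_stochastic(12, 8),
               row_stochastic(12, 9))
  f1 <- fuse_similarities(sims, umkl_params(knn_k = 3))
  f2 <- fuse_similarities(sims[c(2, 3, 1)], umkl_params(knn_k = 3))
  expect_equal(f2$beta, f1$beta[c(2, 3, 1)], tolerance = 1e-6)
  expect_equal(f2$S_final, f1$S_final, tolerance = 1e-8)
})

test_that("single-omic fusion is forced to beta = 1", {
  f <- fuse_similarities(list(row_stochastic(8, 10)), umkl_params(knn_k = 2))
  expect_equal(f$beta, 1)
  expect_equal(f$S_final, row_stochastic(8, 10), tolerance = 1e-12)
})

test_that("asymmetric similarities are symmetrized with a warning", {
  S <- row_stochastic(6, 11)
  S[1, 2] <- S[1, 2] + 0.1
  expect_warning(build_q(list(S), umkl_params(knn_k = 2)), "symmetrized")
})
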