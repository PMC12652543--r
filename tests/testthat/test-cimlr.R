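test_that("simplex projection matches the worked examples and the bisection oracle", {
  expect_equal(simplex_project(c(0.9, 0.3)), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(simplex_project(c(2, 0)), c(1, 0), tolerance = 1e-12)
  feasible <- c(0.2, 0.5, 0.3)
  expect_equal(simplex_project(feasible), feasible, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    v <- stats::rnorm(sample(2:10, 1), sd = 2)
    p <- simplex_project(v)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
    expect_equal(p, oracle_simplex_project(v), tolerance = 1e-8)
  }
})

test_that("the similarity update solves its subproblem exactly (projection oracle)", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    bank <- random_bank(n, 3, seed = i)
    w <- simplex_project(stats::runif(3))
    L <- qr.Q(qr(matrix(stats::rnorm(n * 2), n, 2)))
    params <- cimlr_params(n_clusters = 2, beta = stats::runif(1, 0.5, 2),
                           gamma = stats::runif(1, 0, 2), rho = 0.1)
    S <- update_similarity(bank, w, L, params)
    A <- Reduce(`+`, Map(`*`, bank$kernels, w)) +
      params$gamma * tcrossprod(L)
    for (r in seq_len(n)) {
      expect_equal(S[r, ], oracle_simplex_project(A[r, ] / (2 * params$beta)),
                   tolerance = 1e-6)
    }
  }
  expect_error(update_similarity(random_bank(4, 2, 1), c(0.5, 0.5),
                                 matrix(0, 4, 2),
                                 cimlr_params(2, beta = 0, rho = 1)),
               "beta")
})

test_that("the weight update is the exact entropic minimizer", {
  n <- 6
  bank <- random_bank(n, 4, seed = 3)
  S <- matrix(1 / n, n, n)
  # identical kernels: uniform weights by symmetry
  bank_same <- bank
  for (l in 1:4) bank_same$kernels[[l]] <- bank$kernels[[1]]
  p <- cimlr_params(2, rho = 0.5)
  expect_equal(update_weights(bank_same, S, p), rep(0.25, 4),
               tolerance = 1e-12)
  # engineered gap of exactly rho between two kernels
  b2 <- bank
  b2$kernels <- bank$kernels[1:2]
  rho <- 0.3
  ip1 <- sum(b2$kernels[[1]] * S)
  b2$kernels[[2]] <- b2$kernels[[1]] - (rho / sum(S)) * matrix(1, n, n)
  w <- update_weights(b2, S, cimlr_params(2, rho = rho))
  expect_equal(w[1], exp(1) / (1 + exp(1)), tolerance = 1e-10)
  # rho -> 0 limit: one-hot on the best-aligned kernel
  w0 <- update_weights(bank, S, cimlr_params(2, rho = 1e-8))
  ips <- vapply(bank$kernels, function(K) sum(K * S), numeric(1))
  expect_equal(w0[which.max(ips)], 1, tolerance = 1e-8)
  # independent numerical oracle on the subproblem objective
  obj <- function(w) -sum(w * ips) + 0.5 * sum(ifelse(w > 0, w * log(w), 0))
  w_ours <- update_weights(bank, S, cimlr_params(2, rho = 0.5))
  set.seed(4)
  for (i in 1:20) {
    w_alt <- simplex_project(stats::runif(4))
    expect_gte(obj(w_alt), obj(w_ours) - 1e-10)
  }
})

test_that("the low-rank update attains the spectral optimum", {
  # two 2x2 all-1/4 blocks: eigenvalues (1/2, 1/2, 0, 0)
  S <- matrix(0, 4, 4)
  S[1:2, 1:2] <- 0.25
  S[3:4, 3:4] <- 0.25
  L <- update_lowrank(S, cimlr_params(2, rho = 1))
  expect_equal(sum(L * (S %*% L)), 1.0, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(L) - diag(2))), 1e-8)
  # identity similarity: any orthonormal basis attains C
  L2 <- update_lowrank(diag(5), cimlr_params(3, rho = 1))
  expect_equal(sum(L2 * (diag(5) %*% L2)), 3, tolerance = 1e-10)
  # independent oracle: projector onto the top-C eigenspace via svd
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    A <- matrix(stats::rnorm(n * n), n, n)
    Ssym <- (A + t(A)) / 2
    C <- sample(2:3, 1)
    L <- update_lowrank(Ssym, cimlr_params(C, rho = 1))
    sv <- svd(Ssym + 10 * diag(n))   # shift to order by eigenvalue
    P_oracle <- tcrossprod(sv$u[, seq_len(C)])
    expect_lt(max(abs(tcrossprod(L) - P_oracle)), 1e-6)
  }
})

test_that("permuting samples permutes the low-rank factor", {
  set.seed(6)
  A <- matrix(stats::rnorm(64), 8, 8)
  S <- (A + t(A)) / 2 + 8 * diag(8)
  L <- update_lowrank(S, cimlr_params(3, rho = 1))
  perm <- sample(8)
  Lp <- update_lowrank(S[perm, perm], cimlr_params(3, rho = 1))
  expect_equal(abs(Lp), abs(L[perm, ]), tolerance = 1e-8)
})

test_that("full alternation is monotone and satisfies all constraints", {
  set.seed(7)
  z <- rbind(matrix(stats::rnorm(30 * 5, 0), 30, 5),
             matrix(stats::rnorm(30 * 5, 3), 30, 5))
  bank <- build_bank(z, kernel_grid(sigma_values = c(1, 1.5, 2),
                                    k_values = c(5, 10, 15)))
  res <- learn_similarity(bank, cimlr_params(2))
  tr <- res$objective_trace
  expect_true(all(diff(tr) <= 1e-9))
  expect_true(res$converged)
  expect_equal(rowSums(res$S_row), rep(1, 60), tolerance = 1e-8)
  expect_true(all(res$S_row >= -1e-12))
  expect_equal(sum(res$w), 1, tolerance = 1e-10)
  expect_true(all(res$w >= 0))
  expect_lt(max(abs(crossprod(res$L) - diag(2))), 1e-8)
  expect_lt(max(abs(res$S - t(res$S))), 1e-12)
})

test_that("a single-kernel bank short-circuits to the projected kernel", {
  set.seed(8)
  z <- matrix(stats::rnorm(20 * 3), 20, 3)
  bank <- build_bank(z, kernel_grid(sigma_values = 1, k_values = 5))
  params <- cimlr_params(2, beta = 1, gamma = 0, rho = 0.5, max_iter = 1)
  res <- learn_similarity(bank, params)
  expect_equal(res$w, 1)
  S_expected <- t(apply(bank$kernels[[1]] / 2, 1, simplex_project))
  expect_equal(res$S_row, S_expected, tolerance = 1e-10)
})

test_that("planted blocks come out more similar within than between", {
  set.seed(9)
  z <- rbind(matrix(stats::rnorm(4 * 3, 0, 0.3), 4, 3),
             matrix(stats::rnorm(4 * 3, 4, 0.3), 4, 3))
  bank <- build_bank(z, kernel_grid(sigma_values = c(1, 2),
                                    k_values = c(2, 3)))
  res <- learn_similarity(bank, cimlr_params(2))
  blk <- rep(1:2, each = 4)
  within <- mean(res$S[outer(blk, blk, "==") & !diag(8)])
  between <- mean(res$S[outer(blk, blk, "!=")])
  expect_gt(within, between)
})

test_that("parameter validation rejects degenerate penalties", {
  expect_error(cimlr_params(1), "n_clusters")
  expect_error(cimlr_params(2, beta = -1), "nonnegative")
  expect_error(cimlr_params(2, rho = 0), "rho")
})
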