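# Low-rank fixtures: nonnegative rank-r matrices whose exact reconstruction
# error at width >= r is 0 (truncated-SVD oracle).
lowrank_nonneg <- function(n, p, r, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * r, 0.5, 1.5), n, r)
  B <- matrix(stats::runif(r * p, 0.5, 1.5), r, p)
  A %*% B
}

test_that("masking noise zeroes the configured fraction and nothing else", {
  cfg <- dae_config(input_dropout_rate = 0.1, seed = 1)
  x <- matrix(1, 200, 1000)
  xn <- apply_noise(x, cfg, seed = 42)
  frac <- mean(xn == 0)
  expect_lt(abs(frac - 0.1), 0.01)       # binomial sd ~ 0.00067
  expect_true(all(xn %in% c(0, 1)))
  # rate 0 is the identity
  cfg0 <- dae_config(input_dropout_rate = 0)
  expect_identical(apply_noise(x, cfg0, seed = 1), x)
})

test_that("gaussian corruption adds noise of the requested variance", {
  cfg <- dae_config(noise_kind = "gaussian", gaussian_sigma2 = 4)
  x <- matrix(0, 100, 100)
  xn <- apply_noise(x, cfg, seed = 7)
  expect_lt(abs(stats::var(c(xn)) - 4) / 4, 0.1)
})

test_that("training is deterministic given the seed", {
  x <- lowrank_nonneg(40, 30, 3) + matrix(stats::rnorm(1200, sd = 0.1), 40, 30)
  cfg <- dae_config(epochs = 30, seed = 5, hidden_size_grid = 4)
  f1 <- train_dae(x, cfg)
  f2 <- train_dae(x, cfg)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$W, f2$W)
})

test_that("a noiseless low-rank input is reconstructed almost exactly at sufficient width", {
  # truncated-SVD oracle: at width >= rank the achievable error is 0
  x <- lowrank_nonneg(60, 40, 3, seed = 2)
  sv <- svd(scale(x, scale = FALSE))
  expect_lt(sum(sv$d[-(1:3)]^2) / sum(sv$d^2), 1e-20)
  cfg <- dae_config(input_dropout_rate = 0, l1_penalty = 0, l2_penalty = 0,
                    epochs = 800, learning_rate = 0.05,
                    validation_fraction = 0.2, standardize = FALSE, seed = 3,
                    hidden_size_grid = 8)
  fit <- train_dae(x, cfg)
  input_var <- mean(scale(x, scale = FALSE)^2)
  expect_lt(fit$loss$validation[nrow(fit$loss)], 0.01 * input_var)
})

test_that("insufficient width cannot beat the rank-2 oracle bound", {
  set.seed(4)
  # two orthogonal strong components
  u <- cbind(rep(c(1, 0), each = 20), rep(c(0, 1), each = 20))
  x <- u %*% matrix(stats::runif(2 * 30, 1, 2), 2, 30) +
    matrix(stats::rnorm(40 * 30, sd = 0.01), 40, 30)
  cfg1 <- dae_config(input_dropout_rate = 0, l1_penalty = 0, l2_penalty = 0,
                     epochs = 400, learning_rate = 0.05,
                     validation_fraction = 0.2, seed = 5, hidden_size_grid = 1)
  cfg2 <- dae_config(input_dropout_rate = 0, l1_penalty = 0, l2_penalty = 0,
                     epochs = 400, learning_rate = 0.05,
                     validation_fraction = 0.2, seed = 5, hidden_size_grid = 2)
  mse1 <- train_dae(x, cfg1)$loss$validation
  mse2 <- train_dae(x, cfg2)$loss$validation
  expect_gt(mse1[length(mse1)], mse2[length(mse2)])
})

test_that("training loss trace is finite and decreases overall", {
  x <- lowrank_nonneg(50, 30, 4, seed = 6) +
    matrix(stats::rnorm(1500, sd = 0.05), 50, 30)
  # default sparse regime: random initialization, so there is room to learn
  cfg <- dae_config(epochs = 300, learning_rate = 0.01, seed = 7,
                    hidden_size_grid = 6)
  fit <- train_dae(x, cfg)
  expect_true(all(is.finite(fit$loss$train)))
  expect_lt(fit$loss$train[nrow(fit$loss)], fit$loss$train[1])
})

test_that("encoding is shape-correct, deterministic and row-functional", {
  x <- lowrank_nonneg(30, 25, 3, seed = 8)
  x[5, ] <- x[9, ]   # duplicated samples
  cfg <- dae_config(epochs = 50, seed = 9, hidden_size_grid = 4)
  fit <- train_dae(x, cfg)
  z1 <- encode(x, fit)
  expect_equal(dim(z1), c(30L, 4L))
  expect_identical(unname(z1[5, ]), unname(z1[9, ]))
  expect_identical(z1, encode(x, fit))
  expect_error(encode(x[, 1:10], fit), "feature mismatch")
})

test_that("width grid search follows the held-out reconstruction oracle", {
  x <- lowrank_nonneg(60, 64, 8, seed = 10)
  cfg <- dae_config(input_dropout_rate = 0, l1_penalty = 0, l2_penalty = 0,
                    epochs = 500, learning_rate = 0.05,
                    validation_fraction = 0.2, standardize = FALSE, seed = 11,
                    hidden_size_grid = c(2L, 8L, 32L))
  gs <- grid_search_hidden(x, cfg)
  # widths at or above the true rank reach a small fraction of the rank-2
  # floor (truncated-SVD oracle: error at width >= 8 is exactly 0)
  expect_lt(gs$losses[["8"]], 0.10 * gs$losses[["2"]])
  expect_lt(gs$losses[["32"]], 0.10 * gs$losses[["2"]])
  expect_true(gs$hidden_size %in% c(8L, 32L))
  gs1 <- grid_search_hidden(x, dae_config(hidden_size_grid = 8, epochs = 30,
                                          seed = 1))
  expect_identical(gs1$hidden_size, 8L)
})

test_that("latent structure is invariant to feature order", {
  x <- lowrank_nonneg(40, 30, 3, seed = 12) +
    matrix(stats::rnorm(1200, sd = 0.05), 40, 30)
  cfg <- dae_config(input_dropout_rate = 0, l1_penalty = 0, epochs = 150,
                    seed = 13, hidden_size_grid = 4,
                    validation_fraction = 0.2)
  f1 <- train_dae(x, cfg)
  set.seed(99); perm <- sample(ncol(x))
  f2 <- train_dae(x[, perm], cfg)
  # the reachable reconstruction quality cannot depend on column order
  # (initializations are i.i.d. across features, so traces agree only
  # statistically, not bitwise)
  l1 <- f1$loss$validation[nrow(f1$loss)]
  l2 <- f2$loss$validation[nrow(f2$loss)]
  expect_lt(abs(l1 - l2) / max(l1, l2), 0.2)
})

test_that("config validation guards the documented ranges", {
  expect_error(dae_config(input_dropout_rate = 1), "input_dropout_rate")
  expect_error(dae_config(l1_penalty = -1), "penalties")
  expect_warning(dae_config(hidden_dropout_rate = 0.7), "sensitivity")
  x <- matrix(stats::rnorm(100), 10, 10)
  expect_error(train_dae(x, dae_config(), hidden_size = 10), "smaller")
  expect_error(grid_search_hidden(x, dae_config(validation_fraction = 0,
                                                hidden_size_grid = c(2, 3))),
               "validation_fraction")
})
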