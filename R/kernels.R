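#' The (sigma, k) grid behind the adaptive Gaussian kernel bank
#'
#' Defaults give 5 bandwidth multipliers (1 to 2 by 0.25) crossed with 11
#' neighborhood sizes (10 to 30 by 2): 55 kernels per omic.
#'
#' @param sigma_values bandwidth multipliers.
#' @param k_values nearest-neighbor counts used for the adaptive scale.
#' @return object of class `kernel_grid`.
#' @export
kernel_grid <- function(sigma_values = seq(1, 2, by = 0.25),
                        k_values = seq(10L, 30L, by = 2L)) {
  if (any(k_values < 1)) stop("k_values must be positive")
  structure(list(sigma_values = sigma_values,
                 k_values = as.integer(k_values)),
            class = "kernel_grid")
}

#' Sample-adaptive bandwidths
#'
#' For each sample i, `mu_i` is the mean Euclidean distance to its `k`
#' nearest other samples; the pairwise scale is
#' `eps_ij = sigma * (mu_i + mu_j) / 2`, floored at 1e-10 so duplicate
#' points cannot produce a zero bandwidth.
#'
#' @param z samples x features matrix (latent or raw).
#' @param k neighbor count, `1 <= k < nrow(z)`.
#' @param sigma bandwidth multiplier.
#' @return n x n symmetric matrix of scales (class `kernel_scales`), with the
#'   squared distances attached as `attr(., "d2")`.
#' @export
adaptive_scales <- function(z, k, sigma) {
  stop_if_not_matrix(z)
  n <- nrow(z)
  if (k < 1 || k >= n) stop(sprintf("k must be in [1, %d), got %s", n, k))
  d2 <- sq_dist(z)
  d <- sqrt(d2)
  mu <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i], partial = k)[seq_len(k)])
  }, numeric(1))
  eps <- sigma * outer(mu, mu, "+") / 2
  eps[eps < 1e-10] <- 1e-10
  attr(eps, "d2") <- d2
  class(eps) <- c("kernel_scales", class(eps))
  eps
}

#' Adaptive-bandwidth Gaussian kernel
#'
#' `K_ij = exp(-||z_i - z_j||^2 / (2 eps_ij^2)) / (eps_ij * sqrt(2*pi))`
#' with the scales from [adaptive_scales()]. Unnormalized; see
#' [build_bank()] for the symmetric row normalization used downstream.
#'
#' @param z samples x features matrix.
#' @param scales output of [adaptive_scales()] on the same `z`.
#' @return symmetric n x n kernel matrix.
#' @export
gaussian_kernel <- function(z, scales) {
  d2 <- attr(scales, "d2")
  if (is.null(d2)) d2 <- sq_dist(z)
  if (any(!is.finite(d2))) stop("non-finite pairwise distances")
  eps <- unclass(scales)
  attr(eps, "d2") <- NULL
  K <- exp(-d2 / (2 * eps^2)) / (eps * sqrt(2 * pi))
  (K + t(K)) / 2
}

# Symmetrized row normalization: R = K / rowSums(K), K <- (R + t(R)) / 2.
# Keeps kernels of different bandwidths on comparable scales before they
# compete for weights.
normalize_kernel <- function(K) {
  R <- K / rowSums(K)
  (R + t(R)) / 2
}

#' Build the adaptive Gaussian kernel bank for one omic
#'
#' One kernel per (sigma, k) pair of the grid, in row-major grid order
#' (sigma outer, k inner), each symmetrically row-normalized (disable with
#' `normalize = FALSE`).
#'
#' @param z samples x features matrix.
#' @param grid a [kernel_grid()]; all `k_values` must be `< nrow(z)`.
#' @param normalize apply the symmetric row normalization (default TRUE).
#' @return object of class `kernel_bank`: list with `kernels` (list of n x n
#'   matrices), the `sigma`/`k` tag per kernel, and `sample_ids`.
#' @export
build_bank <- function(z, grid = kernel_grid(), normalize = TRUE) {
  stop_if_not_matrix(z)
  n <- nrow(z)
  if (n <= max(grid$k_values)) {
    stop(sprintf(paste0(
      "n = %d samples but the grid needs k up to %d neighbors; ",
      "shrink k_values (all k must be < n)"), n, max(grid$k_values)))
  }
  d2 <- sq_dist(z)
  d <- sqrt(d2)
  # sorted distances per row, dropping the self-distance (the first zero);
  # mean distance to the k nearest neighbors for every k via prefix sums
  sorted <- t(apply(d, 1, function(r) sort(r)[-1]))
  csum <- t(apply(sorted, 1, cumsum))
  tags <- expand.grid(k = grid$k_values, sigma = grid$sigma_values)
  tags <- tags[order(match(tags$sigma, grid$sigma_values),
                     match(tags$k, grid$k_values)), c("sigma", "k")]
  kernels <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    k <- tags$k[i]; sigma <- tags$sigma[i]
    mu <- csum[, k] / k
    eps <- sigma * outer(mu, mu, "+") / 2
    eps[eps < 1e-10] <- 1e-10
    K <- exp(-d2 / (2 * eps^2)) / (eps * sqrt(2 * pi))
    K <- (K + t(K)) / 2
    if (normalize) K <- normalize_kernel(K)
    kernels[[i]] <- K
  }
  structure(list(kernels = kernels, sigma = tags$sigma, k = tags$k,
                 sample_ids = rownames(z) %||% default_sample_ids(n),
                 normalized = normalize),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("kernel_bank: %d kernels on %d samples (normalized: %s)\n",
              length(x$kernels), length(x$sample_ids), x$normalized))
  invisible(x)
}

# Pool several banks (same samples) into one larger bank, used by the
# joint-kernel baseline.
pool_banks <- function(banks) {
  structure(list(
    kernels = unlist(lapply(banks, `[[`, "kernels"), recursive = FALSE),
    sigma = unlist(lapply(banks, `[[`, "sigma")),
    k = unlist(lapply(banks, `[[`, "k")),
    sample_ids = banks[[1]]$sample_ids,
    normalized = banks[[1]]$normalized),
    class = "kernel_bank")
}
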