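# Fixtures shared across test files; everything is generated in code.

# Block-structured similarity: `sizes[i]` samples in block i, within-block
# similarity `hi`, between-block `lo`, plus optional symmetric jitter.
blocky_similarity <- function(sizes, hi = 0.9, lo = 0.05, jitter = 0,
                              seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- matrix(lo, n, n)
  for (b in seq_along(sizes)) S[lab == b, lab == b] <- hi
  if (jitter > 0) {
    set.seed(seed)
    E <- matrix(stats::rnorm(n * n, sd = jitter), n, n)
    S <- S + (E + t(E)) / 2
    S[S < 1e-3] <- 1e-3
  }
  diag(S) <- hi
  S / rowSums(S) -> R
  (R + t(R)) / 2
}

block_labels <- function(sizes) rep(seq_along(sizes), sizes)

# Small multi-omics dataset for pipeline-level tests (n kept above the
# largest default kernel-grid k of 30).
tiny_sim <- function(seed = 1, spsub = 10, p = 80) {
  sim_config(n_subtypes = 4, samples_per_subtype = spsub, n_features = p,
             signal_ratio = 0.10, noise_variance = 2, mean_shift = 2.5,
             seed = seed)
}

# Independent simplex-projection oracle: solve sum(pmax(v + theta, 0)) = 1
# for theta by bisection (never calls the package's implementation).
oracle_simplex_project <- function(v) {
  f <- function(theta) sum(pmax(v + theta, 0)) - 1
  lo <- -max(v); hi <- -min(v) + 1
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  pmax(v + root, 0)
}

# Squared Euclidean distances between rows (independent of the package's
# internal helper).
sq_dist_for_test <- function(x) {
  as.matrix(stats::dist(x))^2
}

# Random kernel-bank-like object (symmetric positive matrices) for
# subproblem oracle checks.
random_bank <- function(n, n_kernels, seed) {
  set.seed(seed)
  kernels <- lapply(seq_len(n_kernels), function(i) {
    A <- matrix(stats::runif(n * n, 0.05, 1), n, n)
    (A + t(A)) / 2
  })
  structure(list(kernels = kernels, sigma = rep(1, n_kernels),
                 k = rep(2, n_kernels),
                 sample_ids = sprintf("S%02d", seq_len(n)),
                 normalized = FALSE),
            class = "kernel_bank")
}
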