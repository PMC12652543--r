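#' Euclidean projection onto the probability simplex
#'
#' Returns the closest point (in Euclidean norm) to `v` in
#' `{s : s >= 0, sum(s) = 1}` (Held/Duchi algorithm).
#'
#' @param v numeric vector.
#' @return projected vector of the same length.
#' @export
simplex_project <- function(v) {
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Parameters of the per-omic composite-kernel optimization
#'
#' Controls the alternating minimization over a row-stochastic similarity
#' `S`, simplex kernel weights `w`, and an orthonormal low-rank factor `L`:
#' kernel-fit term `-sum_l w_l <K_l, S>`, Frobenius penalty `beta*||S||_F^2`,
#' spectral penalty `gamma*tr(L'(I - S)L)`, and entropy penalty
#' `rho*sum_l w_l log w_l`.
#'
#' @param n_clusters rank C of the low-rank factor (target cluster count).
#' @param beta Frobenius penalty, must be positive (the S-subproblem is
#'   degenerate at 0).
#' @param gamma low-rank penalty.
#' @param rho entropy penalty on kernel weights; `NULL` sets it adaptively
#'   to 0.1 times the median absolute spread of the initial kernel-similarity
#'   inner products (floored at 1e-8).
#' @param max_iter,tol alternation length and relative objective-change
#'   stopping threshold.
#' @return object of class `cimlr_params`.
#' @export
cimlr_params <- function(n_clusters, beta = 1, gamma = 1, rho = NULL,
                         max_iter = 30L, tol = 1e-5) {
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  if (beta < 0 || gamma < 0) stop("beta and gamma must be nonnegative")
  if (!is.null(rho) && rho <= 0) stop("rho must be positive")
  structure(list(n_clusters = as.integer(n_clusters), beta = beta,
                 gamma = gamma, rho = rho, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "cimlr_params")
}

# weighted kernel sum
kernel_mix <- function(bank, w) {
  K <- bank$kernels[[1]] * w[1]
  for (l in seq_along(bank$kernels)[-1]) K <- K + bank$kernels[[l]] * w[l]
  K
}

#' Similarity-matrix update (exact row-wise subproblem solution)
#'
#' Given kernel weights and the low-rank factor, each row of the optimal `S`
#' is the Euclidean projection of `a_i / (2*beta)` onto the probability
#' simplex, where `a_ij = sum_l w_l K_l(i,j) + gamma * (L L')_ij`.
#'
#' @param bank a [build_bank()] kernel bank.
#' @param w kernel weights on the simplex.
#' @param L n x C orthonormal factor.
#' @param params a [cimlr_params()]; `beta` must be > 0.
#' @return row-stochastic n x n matrix.
#' @export
update_similarity <- function(bank, w, L, params) {
  if (params$beta <= 0) {
    stop("beta must be positive: with beta = 0 the similarity subproblem has no bounded minimizer; set a positive Frobenius penalty")
  }
  A <- kernel_mix(bank, w) + params$gamma * tcrossprod(L)
  S <- A / (2 * params$beta)
  t(apply(S, 1, simplex_project))
}

#' Kernel-weight update (exact entropy-regularized subproblem solution)
#'
#' `w_l` proportional to `exp(<K_l, S> / rho)` with `<K_l, S> =
#' sum_ij K_l(i,j) S_ij` — the closed-form minimizer of the linear objective
#' plus entropy on the simplex (softmax), guarded against overflow.
#'
#' @param bank kernel bank.
#' @param S current row-stochastic similarity.
#' @param params a [cimlr_params()] with `rho` resolved to a number.
#' @return weight vector on the simplex.
#' @export
update_weights <- function(bank, S, params) {
  if (is.null(params$rho) || params$rho <= 0) stop("rho must be positive")
  ip <- vapply(bank$kernels, function(K) sum(K * S), numeric(1))
  e <- ip / params$rho
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

#' Low-rank factor update (exact spectral subproblem solution)
#'
#' The minimizer of `tr(L'(I - S)L)` under `L'L = I` is the matrix of top-C
#' eigenvectors of the symmetrized similarity. Column signs follow a fixed
#' convention (largest-magnitude entry positive) so the result is
#' deterministic.
#'
#' @param S n x n similarity.
#' @param params a [cimlr_params()] supplying C.
#' @return n x C matrix with orthonormal columns.
#' @export
update_lowrank <- function(S, params) {
  Ssym <- (S + t(S)) / 2
  es <- eigen(Ssym, symmetric = TRUE)
  L <- es$vectors[, seq_len(params$n_clusters), drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

cimlr_objective <- function(bank, S, L, w, params) {
  ip <- vapply(bank$kernels, function(K) sum(K * S), numeric(1))
  Ssym <- (S + t(S)) / 2
  -sum(w * ip) + params$beta * sum(S^2) +
    params$gamma * (ncol(L) - sum(L * (Ssym %*% L))) +
    params$rho * sum(ifelse(w > 0, w * log(w), 0))
}

#' Learn the composite similarity of one omic
#'
#' Alternates the three exact block updates ([update_similarity()],
#' [update_lowrank()], [update_weights()]) from a deterministic
#' initialization (uniform weights, row-normalized mean kernel, spectral
#' factor) until the relative objective change falls below `tol` or
#' `max_iter` sweeps. Because every block update is an exact minimizer, the
#' objective trace is non-increasing; a violation beyond 1e-9 aborts with
#' the trace attached.
#'
#' @param bank kernel bank from [build_bank()].
#' @param params a [cimlr_params()].
#' @return object of class `similarity_result`: `S` (symmetrized, row sums
#'   1), `w`, `L`, `objective_trace`, the mixed-kernel distance `D`, and a
#'   `converged` flag.
#' @export
learn_similarity <- function(bank, params) {
  nk <- length(bank$kernels)
  if (nk == 0) stop("empty kernel bank")
  n <- nrow(bank$kernels[[1]])
  w <- rep(1 / nk, nk)
  S0 <- kernel_mix(bank, w)
  S0 <- S0 / rowSums(S0)
  if (is.null(params$rho)) {
    ip0 <- vapply(bank$kernels, function(K) sum(K * S0), numeric(1))
    spread <- stats::median(abs(ip0 - stats::median(ip0)))
    params$rho <- max(0.1 * spread, 1e-8)
  }
  L <- update_lowrank(S0, params)
  S <- S0
  trace <- cimlr_objective(bank, S, L, w, params)
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    S <- update_similarity(bank, w, L, params)
    L <- update_lowrank(S, params)
    w <- update_weights(bank, S, params)
    obj <- cimlr_objective(bank, S, L, w, params)
    if (obj > trace[length(trace)] + 1e-9) {
      stop(paste0("objective increased during alternation; trace: ",
                  paste(signif(c(trace, obj), 8), collapse = ", ")))
    }
    rel <- abs(trace[length(trace)] - obj) /
      max(abs(trace[length(trace)]), 1e-12)
    trace <- c(trace, obj)
    if (rel < params$tol) { converged <- TRUE; break }
  }
  D <- 2 - 2 * kernel_mix(bank, w)
  # S_row is the constrained iterate (rows exactly on the simplex); S is the
  # symmetrized matrix handed to fusion and clustering.
  structure(list(S = (S + t(S)) / 2, S_row = S, w = w, L = L,
                 objective_trace = trace, D = D,
                 rho = params$rho, converged = converged,
                 sample_ids = bank$sample_ids),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "similarity_result: %d samples, %d kernels, %d sweeps (converged: %s)\n",
    nrow(x$S), length(x$w), length(x$objective_trace) - 1L, x$converged))
  invisible(x)
}
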