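#' Parameters for unsupervised multiple-kernel fusion
#'
#' @param knn_k neighbor count of the per-omic similarity graphs; default
#'   `ceiling(n/10)` resolved when the graphs are built.
#' @param qp_tol tolerance used in the simplex-QP feasibility checks.
#' @return object of class `umkl_params`.
#' @export
umkl_params <- function(knn_k = NULL, qp_tol = 1e-10) {
  if (!is.null(knn_k) && knn_k < 1) stop("knn_k must be at least 1")
  structure(list(knn_k = knn_k, qp_tol = qp_tol), class = "umkl_params")
}

#' Edge-frequency matrix of the per-omic similarity graphs
#'
#' For each composite similarity `S_m`, builds an undirected kNN graph
#' (edge i-j if j is among i's `knn_k` largest off-diagonal similarities, or
#' vice versa). `Q_ij` counts in how many omics' graphs the pair appears:
#' symmetric, integer-valued, zero diagonal, bounded by the number of omics.
#'
#' @param similarities list of n x n similarity matrices on the same samples.
#' @param params an [umkl_params()].
#' @return integer n x n matrix `Q`.
#' @export
build_q <- function(similarities, params = umkl_params()) {
  n <- nrow(similarities[[1]])
  k <- params$knn_k %||% ceiling(n / 10)
  if (k >= n) stop("knn_k must be smaller than the number of samples")
  Q <- matrix(0L, n, n)
  for (S in similarities) {
    if (max(abs(S - t(S))) > 1e-8) {
      warning("asymmetric similarity symmetrized before graph construction")
      S <- (S + t(S)) / 2
    }
    A <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      s <- S[i, ]
      s[i] <- -Inf
      nb <- order(s, decreasing = TRUE)[seq_len(k)]
      A[i, nb] <- 1L
    }
    A <- pmax(A, t(A))  # union: one-sided neighbors count
    Q <- Q + A
  }
  diag(Q) <- 0L
  Q
}

#' Graph-weighted alignment gram matrix of the omic similarities
#'
#' `G_mm' = sum_ij Q_ij <d_i^m - d_j^m, d_i^m' - d_j^m'>` where `d_i^m` is
#' row i of similarity `S_m`: how coherently two omics displace samples
#' across the edges of the shared topology `Q`.
#'
#' @param similarities list of M similarity matrices.
#' @param Q matrix from [build_q()].
#' @return symmetric M x M matrix with nonnegative diagonal.
#' @export
fusion_gram <- function(similarities, Q) {
  M <- length(similarities)
  G <- matrix(0, M, M)
  q_row <- rowSums(Q)
  for (m in seq_len(M)) {
    for (mp in m:M) {
      C <- tcrossprod(similarities[[m]], similarities[[mp]])
      d <- diag(C)
      val <- 2 * sum(d * q_row) - sum(Q * (C + t(C)))
      G[m, mp] <- val
      G[mp, m] <- val
    }
  }
  G
}

#' Exact simplex-constrained quadratic program for the omic weights
#'
#' Minimizes `beta' G beta` over the probability simplex by enumerating
#' active sets: for every support the equality-constrained stationary point
#' is computed and kept if feasible, vertices included, so the returned
#' minimizer is exact for positive semidefinite `G` (an indefinite gram is
#' nudged by `1e-10 * I` with a warning). Ties are broken toward the uniform
#' weighting.
#'
#' @param gram symmetric M x M matrix from [fusion_gram()].
#' @param params an [umkl_params()].
#' @return weight vector `beta` on the simplex.
#' @export
solve_beta <- function(gram, params = umkl_params()) {
  M <- nrow(gram)
  if (M == 1) return(1)
  if (max(abs(gram - t(gram))) > 1e-8) stop("gram must be symmetric")
  gram <- (gram + t(gram)) / 2
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  scale_ref <- max(abs(ev), 1)
  if (min(ev) < -1e-9 * scale_ref) {
    warning("indefinite gram perturbed by 1e-10 * I")
    gram <- gram + diag(1e-10 * scale_ref, M)
  }
  tol <- params$qp_tol
  best <- NULL; best_obj <- Inf
  cand <- list()
  supports <- unlist(lapply(seq_len(M), function(sz) {
    utils::combn(M, sz, simplify = FALSE)
  }), recursive = FALSE)
  for (A in supports) {
    GA <- gram[A, A, drop = FALSE]
    x <- tryCatch(solve(GA + diag(1e-12 * scale_ref, length(A)),
                        rep(1, length(A))),
                  error = function(e) NULL)
    if (is.null(x) || abs(sum(x)) < tol) next
    bA <- x / sum(x)
    if (any(bA < -1e-9)) next
    beta <- rep(0, M)
    beta[A] <- pmax(bA, 0)
    beta <- beta / sum(beta)
    cand[[length(cand) + 1L]] <- beta
  }
  for (beta in cand) {
    obj <- drop(crossprod(beta, gram %*% beta))
    if (obj < best_obj - 1e-12 ||
        (obj < best_obj + 1e-12 && !is.null(best) &&
         sum((beta - 1 / M)^2) < sum((best - 1 / M)^2))) {
      best <- beta; best_obj <- obj
    }
  }
  best
}

#' Fuse composite similarities with simplex weights
#'
#' Elementwise convex combination `S_final = sum_m beta_m S_m`.
#'
#' @param similarities list of M similarity matrices.
#' @param beta simplex weights of length M.
#' @return n x n fused similarity.
#' @export
fuse <- function(similarities, beta) {
  if (length(beta) != length(similarities)) {
    stop("beta length must match the number of similarities")
  }
  S <- similarities[[1]] * beta[1]
  for (m in seq_along(similarities)[-1]) S <- S + similarities[[m]] * beta[m]
  S
}

#' Full fusion step: graph, gram, weights, fused kernel
#'
#' @param similarities list of per-omic composite similarities (e.g. the `S`
#'   fields of [learn_similarity()] results).
#' @param params an [umkl_params()].
#' @return object of class `fusion_result` with `beta`, `S_final`, `gram`
#'   and `Q`.
#' @export
fuse_similarities <- function(similarities, params = umkl_params()) {
  if (length(similarities) == 1) {
    return(structure(list(beta = 1, S_final = similarities[[1]],
                          gram = matrix(fusion_gram(similarities,
                                                    build_q(similarities, params)), 1, 1),
                          Q = NULL),
                     class = "fusion_result"))
  }
  Q <- build_q(similarities, params)
  gram <- fusion_gram(similarities, Q)
  beta <- solve_beta(gram, params)
  structure(list(beta = beta, S_final = fuse(similarities, beta),
                 gram = gram, Q = Q),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result: %d omics, beta = (%s)\n",
              length(x$beta), paste(signif(x$beta, 4), collapse = ", ")))
  invisible(x)
}
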