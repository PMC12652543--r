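# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  invisible(x)
}

# Squared Euclidean distance matrix between rows of `x` (n x n).
sq_dist <- function(x) {
  rs <- rowSums(x * x)
  d2 <- outer(rs, rs, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

default_sample_ids <- function(n) sprintf("S%03d", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
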