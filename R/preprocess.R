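#' Drop high-missingness features and impute the rest
#'
#' Features (columns) with a missing fraction above `max_missing_fraction`
#' are removed. Remaining gaps are filled by feature-wise KNN imputation:
#' the `impute_k` nearest features by Euclidean distance on co-observed
#' samples supply the mean of their observed values at the gap's sample.
#' Features left entirely missing after filtering are dropped with a
#' message.
#'
#' @param x samples x features matrix; missing entries are `NA` (distinct
#'   from zeros).
#' @param max_missing_fraction per-feature missingness threshold (default
#'   0.30).
#' @param impute_k number of neighbor features (default 10).
#' @return matrix with no missing values and possibly fewer columns.
#' @export
filter_and_impute <- function(x, max_missing_fraction = 0.30, impute_k = 10) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1) {
    stop("max_missing_fraction must be in (0, 1)")
  }
  if (impute_k < 1) stop("impute_k must be at least 1")
  miss_frac <- colMeans(is.na(x))
  x <- x[, miss_frac <= max_missing_fraction, drop = FALSE]
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    message(sprintf("dropping %d feature(s) with no observed values",
                    sum(all_na)))
    x <- x[, !all_na, drop = FALSE]
  }
  gaps <- which(colSums(is.na(x)) > 0)
  if (length(gaps) == 0) return(x)
  p <- ncol(x)
  for (j in gaps) {
    xj <- x[, j]
    obs_j <- !is.na(xj)
    # mean squared difference over co-observed samples, scale-consistent
    # with Euclidean distance
    d <- vapply(seq_len(p), function(l) {
      if (l == j) return(Inf)
      co <- obs_j & !is.na(x[, l])
      if (!any(co)) return(Inf)
      mean((xj[co] - x[co, l])^2)
    }, numeric(1))
    for (i in which(is.na(xj))) {
      avail <- which(is.finite(d) & !is.na(x[i, ]))
      if (length(avail) == 0) {
        x[i, j] <- mean(xj, na.rm = TRUE)
        next
      }
      nb <- avail[order(d[avail])][seq_len(min(impute_k, length(avail)))]
      x[i, j] <- mean(x[i, nb])
    }
  }
  x
}

#' log2(x + 1) transform
#'
#' @param x nonnegative samples x features matrix.
#' @return elementwise `log2(x + 1)`.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative entries: log2(x+1) expects nonnegative data")
  log2(x + 1)
}

#' Keep the most variable features by median absolute deviation
#'
#' Per-feature raw MAD, `median(|x - median(x)|)` (no consistency constant
#' — the ranking is unaffected). The `top_n` features with the largest MAD
#' are kept in their original column order; ties are broken by original
#' order.
#'
#' @param x samples x features matrix.
#' @param top_n number of features to retain.
#' @return matrix with `top_n` columns.
#' @export
mad_select <- function(x, top_n) {
  if (top_n > ncol(x)) {
    stop(sprintf("top_n = %d exceeds the %d available features",
                 top_n, ncol(x)))
  }
  mads <- apply(x, 2, function(v) stats::median(abs(v - stats::median(v, na.rm = TRUE)),
                                               na.rm = TRUE))
  keep <- sort(order(-mads, seq_along(mads))[seq_len(top_n)])
  x[, keep, drop = FALSE]
}

#' Aggregate CpG-level methylation to gene level
#'
#' One output feature per gene, the mean over its mapped CpG columns; CpGs
#' absent from the mapping are dropped (count reported via `message`).
#'
#' @param x samples x CpGs matrix with CpG identifiers as column names.
#' @param map data frame with columns `cpg_id` and `gene_id`.
#' @return samples x genes matrix.
#' @export
aggregate_cpg <- function(x, map) {
  if (!all(c("cpg_id", "gene_id") %in% names(map))) {
    stop("map must have columns cpg_id and gene_id")
  }
  map <- map[map$cpg_id %in% colnames(x), , drop = FALSE]
  if (nrow(map) == 0) stop("no CpG in the mapping matches the matrix columns")
  dropped <- sum(!colnames(x) %in% map$cpg_id)
  if (dropped > 0) message(sprintf("%d unmapped CpG(s) dropped", dropped))
  genes <- sort(unique(map$gene_id))
  out <- vapply(genes, function(g) {
    cols <- map$cpg_id[map$gene_id == g]
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), genes))
  out
}
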