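#' Normalized mutual information between two partitions
#'
#' `NMI(A, B) = I(A, B) / sqrt(H(A) * H(B))` from the empirical joint
#' contingency table, with natural logs (the base cancels) and the
#' convention `0 * log 0 = 0`. If either partition has a single cluster its
#' entropy is 0 and the score is defined as 0, except that two identical
#' single-cluster partitions score 1; when that convention fires the result
#' carries `attr(., "degenerate") = TRUE`.
#'
#' @param a,b integer/factor label vectors of equal length (cluster identity
#'   per sample; the actual label values are irrelevant).
#' @return a number in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 1) stop("empty label vectors")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (ha == 0 || hb == 0) {
    val <- if (ha == 0 && hb == 0) 1 else 0
    attr(val, "degenerate") <- TRUE
    return(val)
  }
  exp_ <- outer(pi_, pj_)
  mi <- sum(ifelse(pij > 0, pij * log(pij / exp_), 0))
  min(max(mi / sqrt(ha * hb), 0), 1)
}
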