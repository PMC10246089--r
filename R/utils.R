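#' Canonicalize community labels
#'
#' Relabels an assignment vector so that community labels are consecutive
#' positive integers in order of first appearance. Names are preserved.
#'
#' @param labels integer (or factor-like) vector of community labels.
#' @return integer vector with labels `1..k`.
#' @export
canonical_labels <- function(labels) {
  out <- match(labels, unique(labels))
  names(out) <- names(labels)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] so that pipeline code and
#' tests share one entry point.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mlcoex <- function(...) stop(..., call. = FALSE)

check_square_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_mlcoex(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_mlcoex(what, " is not symmetric (max asymmetry ",
                format(max(abs(m - t(m)))), ")")
  invisible(TRUE)
}

# sum of B entries within each community, as used by modularity and Louvain
within_community_sum <- function(B, labels) {
  k <- max(labels)
  tot <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    tot <- tot + sum(B[idx, idx])
  }
  tot
}

# collapse a symmetric matrix by summing rows/columns within label groups
aggregate_matrix <- function(B, labels) {
  k <- max(labels)
  M <- matrix(0, nrow(B), k)
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    M[, c] <- if (length(idx) == 1L) B[, idx] else rowSums(B[, idx, drop = FALSE])
  }
  A <- matrix(0, k, k)
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    A[c, ] <- if (length(idx) == 1L) M[idx, ] else colSums(M[idx, , drop = FALSE])
  }
  (A + t(A)) / 2
}
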