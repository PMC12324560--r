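#' Pearson functional connectivity
#'
#' `R x R` matrix of Pearson correlations between all pairs of regional time
#' series. Zero-variance regions get off-diagonal correlations of 0 (with a
#' warning); the diagonal is always 1.
#'
#' @param ts a [parcellated_ts()] or `T x R` matrix.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_fc <- function(ts) {
  X <- ts_matrix(ts)
  if (nrow(X) < 3L) stop("need at least three frames for correlation")
  sds <- apply(X, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("zero-variance region(s): correlations set to 0")
    C[is.na(C)] <- 0
  }
  diag(C) <- 1
  C
}

edge_labels <- function(r) {
  idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  # reorder column-major upper-tri indices to row-major
  ord <- order(idx[, 1L], idx[, 2L])
  paste(idx[ord, 1L], idx[ord, 2L], sep = "_")
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the strictly-upper-triangle entries in row-major order — the
#' canonical edge ordering used throughout the package — giving a vector of
#' length `R * (R - 1) / 2` (37401 at R = 274). `devectorize_upper()` is the
#' inverse, rebuilding a symmetric matrix with the given diagonal.
#'
#' @param cm square symmetric matrix.
#' @param labels attach "i_j" edge names (1-based region indices).
#' @return Numeric vector of length `R(R-1)/2`.
#' @export
vectorize_upper <- function(cm, labels = FALSE) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("input must be square")
  v <- t(cm)[lower.tri(cm)]   # row-major strict upper triangle
  if (labels) names(v) <- edge_labels(nrow(cm))
  v
}

#' @rdname vectorize_upper
#' @param v vector of length `R(R-1)/2`.
#' @param diag value placed on the diagonal (default 1).
#' @export
devectorize_upper <- function(v, diag = 1) {
  m <- length(v)
  r <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(r - round(r)) > 1e-8) stop("length is not R*(R-1)/2 for integer R")
  r <- round(r)
  out <- matrix(0, r, r)
  out[lower.tri(out)] <- v     # fills column-major lower = row-major upper of t
  out <- t(out)
  out <- out + t(out)
  diag(out) <- diag
  out
}
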