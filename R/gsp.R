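check_sc <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("connectome matrix must be square")
  scale <- max(abs(A), 1)
  if (max(abs(A - t(A))) > tol * scale) stop("connectome matrix must be symmetric")
  if (any(A < 0)) stop("connectome weights must be nonnegative")
  if (any(diag(A) != 0)) stop("connectome diagonal must be zero")
  A
}

#' Distance-binned consensus structural connectome
#'
#' Builds a group structural connectivity matrix from per-subject matrices:
#' (1) a binary consensus mask chosen distance-bin-wise — edges are
#' partitioned into `n_bins` equal-count bins of inter-region distance and,
#' within each bin, the edges most consistently present across subjects are
#' kept so that the kept count matches the average per-subject edge count in
#' that bin (ties broken by mean weight, then edge index); (2) the mean
#' weight matrix across subjects. The output is their elementwise product.
#' Binning by distance prevents the consensus from being biased toward short
#' connections. Recompute this matrix from training subjects only when it
#' feeds a prediction pipeline (see [gsp_feature_provider()]).
#'
#' @param sc_list list of symmetric nonnegative `R x R` matrices, zero diagonal.
#' @param distances `R x R` inter-region distance matrix; if `NULL`, a single
#'   global bin is used (with a warning).
#' @param n_bins number of equal-count distance bins (default 50).
#' @return Consensus `R x R` matrix (symmetric, nonnegative, zero diagonal).
#' @export
consensus_sc <- function(sc_list, distances = NULL, n_bins = 50L) {
  if (length(sc_list) == 0L) stop("need at least one subject matrix")
  sc_list <- lapply(sc_list, check_sc)
  r <- nrow(sc_list[[1L]])
  if (any(vapply(sc_list, nrow, 1L) != r)) stop("matrices must share dimensions")
  W <- vapply(sc_list, vectorize_upper, numeric(r * (r - 1) / 2))
  W <- matrix(W, ncol = length(sc_list))
  pres <- W > 0
  freq <- rowMeans(pres)
  mean_w <- rowMeans(W)
  n_edges <- nrow(W)
  if (is.null(distances)) {
    warning("no distances supplied: consensus uses a single global bin")
    bins <- rep(1L, n_edges)
    n_bins <- 1L
  } else {
    d <- vectorize_upper(as.matrix(distances))
    n_bins <- max(1L, min(as.integer(n_bins), n_edges))
    bins <- ceiling(rank(d, ties.method = "first") / (n_edges / n_bins))
    bins <- pmin.int(bins, n_bins)
  }
  keep <- logical(n_edges)
  for (b in seq_len(n_bins)) {
    ix <- which(bins == b)
    if (!length(ix)) next
    target <- round(mean(colSums(pres[ix, , drop = FALSE])))
    if (target <= 0) next
    ord <- ix[order(-freq[ix], -mean_w[ix], ix)]
    keep[ord[seq_len(min(target, length(ord)))]] <- TRUE
  }
  devectorize_upper(ifelse(keep, mean_w, 0), diag = 0)
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}` with `D = diag(rowSums(A))`. Isolated nodes
#' (zero degree) get `L[i, i] = 1` with zero off-diagonals, keeping `L`
#' symmetric positive semi-definite with spectrum in `[0, 2]`.
#'
#' @param sc symmetric nonnegative weight matrix with zero diagonal.
#' @return The `R x R` normalized Laplacian.
#' @export
normalized_laplacian <- function(sc) {
  A <- check_sc(sc)
  if (all(A == 0)) stop("all-zero connectome has no Laplacian")
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - (dinv %o% dinv) * A
  (L + t(L)) / 2
}

#' Structural connectome harmonics (graph spectrum)
#'
#' Eigendecomposition of a normalized Laplacian. Eigenvalues (graph
#' frequencies) are returned in ascending order; each eigenvector's sign is
#' fixed deterministically by making its largest-magnitude component positive
#' (ties broken by first index). `cutoff` splits the harmonics into a
#' low-frequency set (indices `1..cutoff`) and a high-frequency set; the
#' default is `floor(R / 2)` (137 at R = 274).
#'
#' @param laplacian symmetric matrix, typically from [normalized_laplacian()].
#' @param cutoff number of harmonics in the low-frequency band; default
#'   `floor(R / 2)`.
#' @return Object of class `graph_spectrum`: `eigenvalues`, `eigenvectors`
#'   (orthonormal columns), `cutoff`.
#' @export
graph_spectrum <- function(laplacian, cutoff = NULL) {
  L <- as.matrix(laplacian)
  if (nrow(L) != ncol(L) || max(abs(L - t(L))) > 1e-10 * max(abs(L), 1))
    stop("laplacian must be symmetric")
  r <- nrow(L)
  e <- eigen(L, symmetric = TRUE)
  ord <- seq.int(r, 1L)                 # eigen() returns descending order
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(r)) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  cutoff <- as.integer(cutoff %||% floor(r / 2))
  if (cutoff < 1L || cutoff > r - 1L)
    stop("cutoff must lie in [1, R - 1]")
  structure(list(eigenvalues = vals, eigenvectors = vecs, cutoff = cutoff),
            class = "graph_spectrum")
}

#' @export
print.graph_spectrum <- function(x, ...) {
  r <- length(x$eigenvalues)
  cat(sprintf("Graph spectrum: %d harmonics, eigenvalues in [%.4f, %.4f], cutoff %d\n",
              r, min(x$eigenvalues), max(x$eigenvalues), x$cutoff))
  invisible(x)
}

#' Graph Fourier transform and its inverse
#'
#' `gft()` projects each time frame onto the connectome harmonics
#' (`xhat = U' x`); `igft()` maps graph-domain coefficients back to region
#' space. Because the harmonic basis is orthonormal the round trip is exact
#' and energy is preserved per frame (Parseval).
#'
#' @param x `T x R` matrix (or [parcellated_ts()]) of regional signal /
#'   graph coefficients.
#' @param spectrum a [graph_spectrum()].
#' @return A `T x R` matrix of graph coefficients (`gft`) or regional signal
#'   (`igft`).
#' @export
gft <- function(x, spectrum) {
  X <- if (inherits(x, "parc_ts")) x$data else as.matrix(x)
  if (ncol(X) != nrow(spectrum$eigenvectors))
    stop("column count must equal the number of regions")
  X %*% spectrum$eigenvectors
}

#' @rdname gft
#' @export
igft <- function(x, spectrum) {
  X <- as.matrix(x)
  if (ncol(X) != nrow(spectrum$eigenvectors))
    stop("column count must equal the number of regions")
  tcrossprod(X, spectrum$eigenvectors)
}

#' Graph power spectral density
#'
#' Energy per connectome harmonic of the temporally demeaned signal:
#' `PSD_k = sqrt(sum_t xhat_k(t)^2)`, the l2 norm over time of the k-th graph
#' coefficient series. `mode = "mean_square"` divides the summed squares by T
#' before the square root (a per-frame normalization).
#'
#' @param ts `T x R` matrix or [parcellated_ts()].
#' @param spectrum a [graph_spectrum()].
#' @param mode `"norm"` (default) or `"mean_square"`.
#' @param demean subtract each region's temporal mean first (default `TRUE`).
#' @return A `feature_vector` of length R (one value per harmonic).
#' @export
graph_psd <- function(ts, spectrum, mode = c("norm", "mean_square"),
                      demean = TRUE) {
  mode <- match.arg(mode)
  X <- if (inherits(ts, "parc_ts")) ts$data else as.matrix(ts)
  if (demean) X <- sweep(X, 2L, colMeans(X))
  xhat <- gft(X, spectrum)
  ss <- colSums(xhat^2)
  if (mode == "mean_square") ss <- ss / nrow(X)
  feature_vector(sqrt(ss), "psd",
                 if (inherits(ts, "parc_ts")) ts$subject_id else NA_character_)
}

#' Graph low-/high-pass filtering
#'
#' Zeroes the graph coefficients outside the requested band and maps back to
#' region space: low-pass keeps harmonics `1..cutoff` (signal coupled to
#' structure), high-pass keeps `cutoff+1..R` (signal decoupled from
#' structure). The two outputs sum to the input exactly.
#'
#' @inheritParams graph_psd
#' @param mode `"low"` or `"high"`.
#' @return A `T x R` matrix (or `parc_ts` if the input was one).
#' @export
graph_filter <- function(ts, spectrum, mode = c("low", "high")) {
  mode <- match.arg(mode)
  r <- length(spectrum$eigenvalues)
  c0 <- spectrum$cutoff
  if (c0 < 1L || c0 > r - 1L) stop("cutoff must lie in [1, R - 1]")
  X <- if (inherits(ts, "parc_ts")) ts$data else as.matrix(ts)
  xhat <- gft(X, spectrum)
  if (mode == "low") xhat[, seq.int(c0 + 1L, r)] <- 0
  else xhat[, seq_len(c0)] <- 0
  out <- igft(xhat, spectrum)
  if (inherits(ts, "parc_ts"))
    parcellated_ts(out, tr = ts$tr, session_lengths = ts$session_lengths,
                   subject_id = ts$subject_id)
  else out
}

# FC of one graph-frequency band. Regions whose filtered variance is
# numerical residue relative to the input scale are degenerate: they are
# zeroed so their correlations become 0 under pearson_fc's rule.
band_fc <- function(ts, spectrum, mode) {
  X <- if (inherits(ts, "parc_ts")) ts$data else as.matrix(ts)
  Xf <- graph_filter(X, spectrum, mode)
  ref <- max(apply(X, 2L, stats::sd), .Machine$double.eps)
  sds <- apply(Xf, 2L, stats::sd)
  Xf[, sds < 1e-10 * ref] <- 0
  pearson_fc(Xf)
}

#' Coupled and decoupled functional connectivity
#'
#' Pearson FC of the graph low-pass filtered signal (coupled FC: interactions
#' carried by structure-aligned activity) and of the high-pass filtered
#' signal (decoupled FC). Zero-variance filtered regions get correlation 0.
#'
#' @inheritParams graph_psd
#' @return List with `coupled` and `decoupled` correlation matrices and their
#'   row-major upper-triangle vectors `coupled_vec`, `decoupled_vec`.
#' @export
coupled_decoupled_fc <- function(ts, spectrum) {
  coupled <- band_fc(ts, spectrum, "low")
  decoupled <- band_fc(ts, spectrum, "high")
  list(coupled = coupled, decoupled = decoupled,
       coupled_vec = vectorize_upper(coupled),
       decoupled_vec = vectorize_upper(decoupled))
}

#' Structural decoupling index
#'
#' Per region, the ratio of the temporal l2 norm of the graph high-pass
#' filtered signal to that of the low-pass filtered signal. High values mean
#' activity decoupled from the structural scaffold. Reported as the raw
#' ratio; `log2 = TRUE` returns `log2(ratio)` for compatibility with the
#' original SDI literature.
#'
#' @inheritParams graph_psd
#' @param log2 return the base-2 logarithm of the ratio.
#' @param max_value value assigned when the low-pass norm is numerically zero
#'   (default `1e6`).
#' @return A `feature_vector` of length R.
#' @export
sdi <- function(ts, spectrum, log2 = FALSE, max_value = 1e6, demean = TRUE) {
  X <- if (inherits(ts, "parc_ts")) ts$data else as.matrix(ts)
  if (demean) X <- sweep(X, 2L, colMeans(X))
  low <- graph_filter(X, spectrum, "low")
  high <- graph_filter(X, spectrum, "high")
  nl <- sqrt(colSums(low^2))
  nh <- sqrt(colSums(high^2))
  eps <- 1e-12 * max(nl, nh, 1e-300)
  bad <- nl < eps
  val <- ifelse(bad, max_value, nh / pmax(nl, eps))
  if (any(bad))
    warning("region(s) with numerically zero low-pass energy: SDI capped at max_value")
  if (log2) val <- base::log2(val)
  feature_vector(val, "sdi",
                 if (inherits(ts, "parc_ts")) ts$subject_id else NA_character_)
}
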