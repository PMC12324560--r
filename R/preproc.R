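#' Parcellated BOLD time series
#'
#' Container for a subject's region-averaged fMRI signal: a `T x R` matrix
#' (rows = frames, columns = regions) together with the repetition time and
#' the per-session frame counts. All feature extractors and the preprocessing
#' operations accept this class (plain matrices are coerced with
#' `session_lengths = nrow(x)`).
#'
#' @param data numeric `T x R` matrix of BOLD values (arbitrary units).
#' @param tr repetition time in seconds (default 0.72).
#' @param session_lengths integer vector of per-session frame counts summing
#'   to `nrow(data)`; default a single session.
#' @param subject_id optional subject label.
#' @return An object of class `parc_ts`.
#' @export
parcellated_ts <- function(data, tr = 0.72, session_lengths = nrow(data),
                           subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("time series must be numeric and finite")
  session_lengths <- as.integer(session_lengths)
  if (sum(session_lengths) != nrow(data))
    stop("session_lengths must sum to the number of frames")
  if (any(session_lengths <= 0L)) stop("session lengths must be positive")
  if (tr <= 0) stop("tr must be positive")
  structure(list(data = data, tr = tr, session_lengths = session_lengths,
                 subject_id = subject_id),
            class = "parc_ts")
}

as_parc_ts <- function(x, tr = 0.72) {
  if (inherits(x, "parc_ts")) return(x)
  parcellated_ts(as.matrix(x), tr = tr)
}

#' @export
print.parc_ts <- function(x, ...) {
  cat(sprintf("Parcellated time series: %d frames x %d regions, TR = %g s, %d session(s)\n",
              nrow(x$data), ncol(x$data), x$tr, length(x$session_lengths)))
  invisible(x)
}

# row indices of each session
session_index <- function(ts) {
  ends <- cumsum(ts$session_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' Discard initial frames
#'
#' Removes the first `n_discard` frames of the first session (scanner
#' equilibration/drift frames). With `per_session = TRUE` the same number of
#' frames is dropped at the start of every session.
#'
#' @param ts a [parcellated_ts()] object.
#' @param n_discard number of frames to drop (default 6).
#' @param per_session drop from every session rather than only the first.
#' @return A `parc_ts` with updated data and session lengths.
#' @export
discard_initial_frames <- function(ts, n_discard = 6L, per_session = FALSE) {
  ts <- as_parc_ts(ts)
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be nonnegative")
  if (n_discard == 0L) return(ts)
  sess <- session_index(ts)
  which_sessions <- if (per_session) seq_along(sess) else 1L
  if (any(ts$session_lengths[which_sessions] <= n_discard))
    stop("n_discard must be smaller than the session length")
  drop <- unlist(lapply(sess[which_sessions], function(ix) ix[seq_len(n_discard)]))
  lens <- ts$session_lengths
  lens[which_sessions] <- lens[which_sessions] - n_discard
  parcellated_ts(ts$data[-drop, , drop = FALSE], tr = ts$tr,
                 session_lengths = lens, subject_id = ts$subject_id)
}

# Discrete cosine high-pass basis: regressors spanning periods longer than
# 1/cutoff_hz. K = floor(2 * T * TR * cutoff_hz) components (SPM convention).
dct_basis <- function(n, tr, cutoff_hz) {
  k_max <- floor(2 * n * tr * cutoff_hz)
  if (k_max < 1L) return(NULL)
  t_idx <- 2 * seq_len(n) - 1
  vapply(seq_len(k_max),
         function(k) cos(pi * k * t_idx / (2 * n)),
         numeric(n))
}

# backward differences, first row zero-padded (length preserved)
backward_diff <- function(x) {
  x <- as.matrix(x)
  rbind(matrix(0, 1L, ncol(x)), diff(x))
}

#' Nuisance regression with detrending and temporal high-pass
#'
#' Cleans a parcellated time series by projecting out, in one joint
#' least-squares regression per session: an intercept, an optional linear
#' trend, the supplied confound regressors plus their first-order backward
#' difference derivatives, and a discrete-cosine basis spanning periods longer
#' than `1/highpass_hz`. Because a single projection is used, the result does
#' not depend on any step ordering and is idempotent.
#'
#' @param ts a [parcellated_ts()] object.
#' @param confounds optional `T x C` matrix/data.frame of confound regressors
#'   (e.g. six motion parameters), aligned with the rows of `ts$data`.
#' @param highpass_hz high-pass cutoff in Hz (default 0.01); `NULL` or 0
#'   disables temporal filtering.
#' @param detrend include a linear trend regressor (default `TRUE`).
#' @param add_derivatives include backward-difference derivatives of the
#'   confounds (default `TRUE`).
#' @return A `parc_ts` of residuals; each session's columns have zero mean.
#' @export
nuisance_regress <- function(ts, confounds = NULL, highpass_hz = 0.01,
                             detrend = TRUE, add_derivatives = TRUE) {
  ts <- as_parc_ts(ts)
  Y <- ts$data
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nrow(Y))
      stop("confound rows must match time-series rows")
  }
  out <- Y
  for (ix in session_index(ts)) {
    n <- length(ix)
    X <- matrix(1, n, 1L)
    if (detrend) X <- cbind(X, seq_len(n) - (n + 1) / 2)
    if (!is.null(confounds)) {
      cf <- confounds[ix, , drop = FALSE]
      X <- cbind(X, cf)
      if (add_derivatives) X <- cbind(X, backward_diff(cf))
    }
    if (!is.null(highpass_hz) && highpass_hz > 0) {
      dct <- dct_basis(n, ts$tr, highpass_hz)
      if (!is.null(dct)) X <- cbind(X, dct)
    }
    qx <- qr(X)
    if (qx$rank < ncol(X))
      warning("rank-deficient nuisance design; least-squares projection is unaffected")
    out[ix, ] <- qr.resid(qx, Y[ix, , drop = FALSE])
  }
  parcellated_ts(out, tr = ts$tr, session_lengths = ts$session_lengths,
                 subject_id = ts$subject_id)
}
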