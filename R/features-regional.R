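FEATURE_NAMES <- c("mean", "sd", "mssd", "falff", "fc", "psd", "sdi",
                   "coupled_fc", "decoupled_fc")

feature_vector <- function(values, name, subject_id = NA_character_) {
  structure(as.numeric(values), feature = name, subject_id = subject_id,
            names = names(values), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Feature '%s' (%d values)\n", attr(x, "feature"), length(x)))
  print(utils::head(as.numeric(x), 8L))
  invisible(x)
}

ts_matrix <- function(ts) as_parc_ts(ts)$data

#' Regional mean and standard deviation
#'
#' Per-region temporal mean and sample standard deviation (denominator
#' `N - 1`) of the concatenated time series.
#'
#' @param ts a [parcellated_ts()] or `T x R` matrix.
#' @return `regional_mean`/`regional_sd`: a `feature_vector` of length R.
#'   `regional_mean_sd`: a list with both.
#' @export
regional_mean <- function(ts) {
  ts <- as_parc_ts(ts)
  feature_vector(colMeans(ts$data), "mean", ts$subject_id)
}

#' @rdname regional_mean
#' @export
regional_sd <- function(ts) {
  ts <- as_parc_ts(ts)
  X <- ts$data
  if (nrow(X) < 2L) stop("need at least two frames")
  v <- colSums(sweep(X, 2L, colMeans(X))^2) / (nrow(X) - 1L)
  feature_vector(sqrt(v), "sd", ts$subject_id)
}

#' @rdname regional_mean
#' @export
regional_mean_sd <- function(ts) list(mean = regional_mean(ts), sd = regional_sd(ts))

#' BOLD variability: mean squared successive difference
#'
#' Per region, `MSSD = 1/(N-1) * sum_{i=1}^{N-1} (x_{i+1} - x_i)^2`, the
#' moment-to-moment change of the signal. Sessions are concatenated before
#' the differences are taken.
#'
#' @inheritParams regional_mean
#' @return A `feature_vector` of length R.
#' @export
mssd <- function(ts) {
  ts <- as_parc_ts(ts)
  X <- ts$data
  if (nrow(X) < 2L) stop("need at least two frames")
  feature_vector(colSums(diff(X)^2) / (nrow(X) - 1L), "mssd", ts$subject_id)
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Ratio of the spectral amplitude in a low-frequency band (default
#' 0.01-0.08 Hz) to the amplitude over the whole positive-frequency range of
#' the demeaned, concatenated series. `mode = "amplitude"` (default) sums FFT
#' magnitudes; `mode = "power"` sums squared magnitudes.
#'
#' @inheritParams regional_mean
#' @param band closed frequency band in Hz, default `c(0.01, 0.08)`.
#' @param mode `"amplitude"` or `"power"`.
#' @return A `feature_vector` of length R with values in `[0, 1]`;
#'   zero-variance regions give 0 with a warning.
#' @export
falff <- function(ts, band = c(0.01, 0.08), mode = c("amplitude", "power")) {
  ts <- as_parc_ts(ts)
  mode <- match.arg(mode)
  X <- ts$data
  n <- nrow(X)
  if (n < 16L) stop("need at least 16 frames for a spectral estimate")
  nyq <- 1 / (2 * ts$tr)
  if (band[2] >= nyq) stop("band upper edge must be below the Nyquist frequency")
  X <- sweep(X, 2L, colMeans(X))
  amp <- Mod(stats::mvfft(X))
  pos <- seq.int(2L, floor(n / 2) + 1L)    # positive-frequency bins
  freqs <- (pos - 1L) / (n * ts$tr)
  amp <- amp[pos, , drop = FALSE]
  if (mode == "power") amp <- amp^2
  in_band <- freqs >= band[1] & freqs <= band[2]
  tot <- colSums(amp)
  val <- ifelse(tot > 0, colSums(amp[in_band, , drop = FALSE]) / tot, 0)
  if (any(tot == 0))
    warning("zero-variance region(s): fALFF set to 0")
  feature_vector(val, "falff", ts$subject_id)
}
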