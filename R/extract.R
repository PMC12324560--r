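#' Extract one feature for every subject
#'
#' Applies one of the nine feature extractors to each subject's time series
#' and stacks the results into a subjects-by-features matrix ready for
#' prediction. Regional features (`mean`, `sd`, `mssd`, `falff`, `psd`,
#' `sdi`) give R columns; edge features (`fc`, `coupled_fc`, `decoupled_fc`)
#' give `R(R-1)/2` columns in the canonical row-major upper-triangle order.
#' The graph features require a [graph_spectrum()].
#'
#' @param ts_list named list of [parcellated_ts()] objects.
#' @param feature one of `mean`, `sd`, `mssd`, `falff`, `fc`, `psd`, `sdi`,
#'   `coupled_fc`, `decoupled_fc`.
#' @param spectrum a [graph_spectrum()]; required for `psd`, `sdi`,
#'   `coupled_fc`, `decoupled_fc`.
#' @param falff_band fALFF frequency band (Hz).
#' @return Numeric matrix, rownames = subject ids.
#' @export
extract_features <- function(ts_list, feature, spectrum = NULL,
                             falff_band = c(0.01, 0.08)) {
  feature <- match.arg(feature, FEATURE_NAMES)
  needs_spectrum <- feature %in% c("psd", "sdi", "coupled_fc", "decoupled_fc")
  if (needs_spectrum && is.null(spectrum))
    stop("feature '", feature, "' requires a graph spectrum")
  rows <- lapply(ts_list, function(ts) {
    ts <- as_parc_ts(ts)
    switch(feature,
      mean = as.numeric(regional_mean(ts)),
      sd = as.numeric(regional_sd(ts)),
      mssd = as.numeric(mssd(ts)),
      falff = as.numeric(suppressWarnings(falff(ts, band = falff_band))),
      fc = vectorize_upper(pearson_fc(ts)),
      psd = as.numeric(graph_psd(ts, spectrum)),
      sdi = as.numeric(suppressWarnings(sdi(ts, spectrum))),
      coupled_fc = vectorize_upper(suppressWarnings(
        band_fc(ts, spectrum, "low"))),
      decoupled_fc = vectorize_upper(suppressWarnings(
        band_fc(ts, spectrum, "high"))))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(ts_list)
  colnames(X) <- if (feature %in% c("fc", "coupled_fc", "decoupled_fc"))
    edge_labels(round((1 + sqrt(1 + 8 * ncol(X))) / 2))
  else paste0("r", seq_len(ncol(X)))
  X
}

#' Split-aware provider for graph-signal-processing features
#'
#' The consensus structural connectome must be rebuilt from training subjects
#' only, so GSP features depend on the train/test split. This returns a
#' function `f(train_ids)` that (1) builds the distance-binned consensus SC
#' from the training subjects' matrices, (2) decomposes its normalized
#' Laplacian, and (3) extracts the requested feature for *all* subjects under
#' that spectrum. Pass the provider as the `x` argument of [bb_predict()].
#'
#' @param ts_list named list of [parcellated_ts()] objects (all subjects).
#' @param sc_list named list of subject SC matrices (same names).
#' @param distances inter-region distance matrix for consensus binning.
#' @param feature `psd`, `sdi`, `coupled_fc`, or `decoupled_fc`.
#' @param n_bins consensus distance bins (default 50).
#' @param cutoff graph-frequency cutoff; default `floor(R / 2)`.
#' @return A function of `train_ids` returning the full feature matrix.
#' @export
gsp_feature_provider <- function(ts_list, sc_list, distances, feature,
                                 n_bins = 50L, cutoff = NULL) {
  feature <- match.arg(feature, c("psd", "sdi", "coupled_fc", "decoupled_fc"))
  force(ts_list); force(sc_list); force(distances)
  function(train_ids) {
    cs <- consensus_sc(sc_list[train_ids], distances, n_bins = n_bins)
    gs <- graph_spectrum(normalized_laplacian(cs), cutoff = cutoff)
    extract_features(ts_list, feature, spectrum = gs)
  }
}
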