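#' Truncate a recording to a scan-time fraction
#'
#' Keeps the first `floor(session_amount * frames_per_session)` frames,
#' counted from the start of session one across the concatenated sessions
#' (so `session_amount = 2` is exactly sessions one and two). Session
#' boundaries are preserved in the output's `session_lengths`.
#'
#' @param ts a [parcellated_ts()].
#' @param session_amount positive amount in session units (e.g. 0.25, 1, 4).
#' @return A truncated `parc_ts`.
#' @export
truncate_scan <- function(ts, session_amount) {
  ts <- as_parc_ts(ts)
  fps <- ts$session_lengths[1L]
  n_keep <- floor(session_amount * fps)
  total <- sum(ts$session_lengths)
  if (session_amount <= 0 || n_keep < 1L) stop("session_amount too small")
  if (n_keep > total) stop("session_amount exceeds the available data")
  lens <- integer(0)
  left <- n_keep
  for (l in ts$session_lengths) {
    take <- min(l, left)
    if (take > 0L) lens <- c(lens, take)
    left <- left - take
    if (left == 0L) break
  }
  parcellated_ts(ts$data[seq_len(n_keep), , drop = FALSE], tr = ts$tr,
                 session_lengths = lens, subject_id = ts$subject_id)
}

#' Subsample the training set of a split
#'
#' Selects a family-respecting subset of training subjects whose size is
#' closest to `fraction` of the training set; the test set is untouched.
#' For a fixed seed the subsets are nested across fractions (the families
#' are shuffled once and a prefix is taken), which reduces variance across
#' the cells of a scaling grid.
#'
#' @param split one element of [make_family_splits()].
#' @param cohort cohort data.frame with `subject_id`, `family_id`.
#' @param fraction target training fraction in (0, 1].
#' @param seed seed for the family shuffle (keep constant across fractions
#'   for nestedness).
#' @return A split with the reduced `train_ids` (original order preserved).
#' @export
subsample_train <- function(split, cohort, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(split)
  fams <- cohort$family_id[match(split$train_ids, cohort$subject_id)]
  ufam <- unique(fams)
  ufam <- with_seed(seed, sample_vec(ufam))
  sizes <- as.integer(table(fams)[ufam])
  cum <- cumsum(sizes)
  target <- fraction * length(split$train_ids)
  k <- which.min(abs(cum - target))
  if (cum[k] < 1L) stop("fraction too small: no family fits")
  keep_f <- ufam[seq_len(k)]
  out <- split
  out$train_ids <- split$train_ids[fams %in% keep_f]
  out
}

#' Scaling experiments over training-set size and scan time
#'
#' Reruns the prediction pipeline for every combination of a training-set
#' fraction and a scan-time amount: within a cell the time series of all
#' subjects are truncated to the scan amount, features are recomputed from
#' the truncated data, the training set of each split is subsampled
#' (family-respecting, nested across fractions), and the model is refit and
#' scored. Split seeds are shared across cells, the test subjects are
#' identical in every cell, and the cell `(1, max sessions)` reproduces the
#' plain [bb_predict()] run exactly.
#'
#' @param ts_list named list of [parcellated_ts()] (all subjects).
#' @param y target vector or cohort column name.
#' @param cohort cohort data.frame.
#' @param feature feature name (see [extract_features()]).
#' @param model model name or [model_spec()].
#' @param train_fractions training-set fractions (default 0.2..1 by 0.2).
#' @param session_amounts scan amounts in session units (default
#'   0.25, 0.5, 1, 2, 4).
#' @param sc_list,distances,n_bins,cutoff consensus-SC inputs, required for
#'   graph features (`psd`, `sdi`, `coupled_fc`, `decoupled_fc`); the
#'   consensus is rebuilt per training split inside every cell.
#' @param spectrum optional fixed [graph_spectrum()] used for graph features
#'   instead of per-split consensus rebuilding.
#' @param n_splits,test_frac,seed evaluation design, as in [bb_predict()].
#' @return Object of class `bb_scaling`: long-format results plus heatmap
#'   and curve tables; see `print`, `plot`, `as.data.frame` methods.
#' @export
run_scaling <- function(ts_list, y, cohort, feature, model = "elastic_net",
                        train_fractions = seq(0.2, 1, by = 0.2),
                        session_amounts = c(0.25, 0.5, 1, 2, 4),
                        sc_list = NULL, distances = NULL, n_bins = 50L,
                        cutoff = NULL, spectrum = NULL,
                        n_splits = 10L, test_frac = 0.15, seed = 1L) {
  model <- as_model_spec(model)
  if (is.character(y) && length(y) == 1L) y <- cohort[[y]]
  needs_gsp <- feature %in% c("psd", "sdi", "coupled_fc", "decoupled_fc")
  if (needs_gsp && is.null(spectrum) && (is.null(sc_list) || is.null(distances)))
    stop("graph features need either a spectrum or sc_list + distances")
  splits <- make_family_splits(cohort, n_splits, test_frac,
                               seed = substream_seed(seed, "splits"))
  rows <- list()
  for (sa in session_amounts) {
    ts_cell <- lapply(ts_list, truncate_scan, session_amount = sa)
    x_cell <- if (!needs_gsp) {
      extract_features(ts_cell, feature)
    } else if (!is.null(spectrum)) {
      extract_features(ts_cell, feature, spectrum = spectrum)
    } else {
      gsp_feature_provider(ts_cell, sc_list, distances, feature,
                           n_bins = n_bins, cutoff = cutoff)
    }
    for (fr in train_fractions) {
      for (s in seq_along(splits)) {
        sp <- subsample_train(splits[[s]], cohort, fr,
                              seed = substream_seed(seed,
                                paste0("sub_", splits[[s]]$split_id)))
        res <- tryCatch(
          fit_evaluate(x_cell, y, sp, model, cohort,
                       seed = substream_seed(seed,
                         paste0("inner_", sp$split_id))),
          error = function(e)
            stop(sprintf("scaling cell (fraction=%g, sessions=%g, split=%d): %s",
                         fr, sa, sp$split_id, conditionMessage(e)),
                 call. = FALSE))
        rows[[length(rows) + 1L]] <-
          data.frame(train_fraction = fr, session_amount = sa,
                     split = sp$split_id, n_train = length(sp$train_ids),
                     n_test = length(sp$test_ids), metric = res$metric)
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(metric ~ train_fraction + session_amount, long,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg <- cbind(agg[, 1:2], agg$metric)
  heat <- stats::xtabs(mean ~ train_fraction + session_amount, agg)
  heat <- array(as.numeric(heat), dim = dim(heat), dimnames = dimnames(heat))
  tr <- as_parc_ts(ts_list[[1L]])$tr
  fps <- as_parc_ts(ts_list[[1L]])$session_lengths[1L]
  curve <- agg
  curve$scan_minutes <- curve$session_amount * fps * tr / 60
  structure(list(long = long, cell_stats = agg, heatmap = heat,
                 curve = curve, feature = feature, model = model$name,
                 task = model$task, seed = seed,
                 train_fractions = train_fractions,
                 session_amounts = session_amounts),
            class = "bb_scaling")
}

#' @export
print.bb_scaling <- function(x, ...) {
  cat(sprintf("Scaling grid for feature '%s' [%s]: %d x %d cells, %d splits each\n",
              x$feature, x$model, length(x$train_fractions),
              length(x$session_amounts), max(x$long$split)))
  cat("Mean test metric (rows = training fraction, cols = sessions):\n")
  print(round(x$heatmap, 3))
  invisible(x)
}

#' @export
as.data.frame.bb_scaling <- function(x, ...) x$long

#' @export
plot.bb_scaling <- function(x, which = c("heatmap", "curve"), ...) {
  which <- match.arg(which)
  mname <- if (x$task == "regression") "R^2" else "accuracy"
  if (which == "heatmap") {
    z <- unclass(x$heatmap)
    graphics::image(x = seq_along(x$train_fractions),
                    y = seq_along(x$session_amounts), z = z,
                    xlab = "training fraction", ylab = "sessions",
                    axes = FALSE, main = sprintf("mean %s (%s, %s)",
                                                 mname, x$feature, x$model),
                    col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
    graphics::axis(1, seq_along(x$train_fractions), x$train_fractions)
    graphics::axis(2, seq_along(x$session_amounts), x$session_amounts)
    graphics::box()
  } else {
    cs <- x$curve
    graphics::plot(range(cs$scan_minutes * cs$train_fraction),
                   range(cs$mean), type = "n",
                   xlab = "total training scan time (subject-weighted min)",
                   ylab = mname,
                   main = sprintf("scaling curves (%s, %s)", x$feature, x$model))
    cols <- grDevices::hcl.colors(length(x$session_amounts), "Dark 3")
    for (i in seq_along(x$session_amounts)) {
      sub <- cs[cs$session_amount == x$session_amounts[i], ]
      graphics::lines(sub$scan_minutes * sub$train_fraction, sub$mean,
                      col = cols[i], lwd = 2, type = "b", pch = 16)
    }
    graphics::legend("bottomright", legend = x$session_amounts,
                     title = "sessions", col = cols, lwd = 2, cex = 0.8)
  }
  invisible(x)
}
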