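#' Family-grouped train/test splits
#'
#' Draws `n_splits` independent random splits in which every family is
#' assigned whole to either the training or the test set (heritable traits
#' leak across family members, so family-aware splitting is required for an
#' honest test estimate). Families are shuffled and a prefix whose cumulative
#' size is closest to `test_frac * n` becomes the test set, so realized test
#' sizes vary slightly around the target.
#'
#' @param cohort data.frame with `subject_id` and `family_id` columns.
#' @param n_splits number of splits (default 10).
#' @param test_frac target test fraction (default 0.15).
#' @param seed integer seed.
#' @return List of splits, each `list(split_id, train_ids, test_ids, seed)`.
#' @export
make_family_splits <- function(cohort, n_splits = 10L, test_frac = 0.15,
                               seed = 1L) {
  stopifnot(all(c("subject_id", "family_id") %in% names(cohort)))
  n <- nrow(cohort)
  fam_sizes <- table(cohort$family_id)
  if (max(fam_sizes) > (1 - test_frac) * n)
    stop("a single family exceeds the available training fraction")
  target <- round(test_frac * n)
  lapply(seq_len(n_splits), function(s) {
    sseed <- substream_seed(seed, paste0("split_", s))
    with_seed(sseed, {
      fams <- sample_vec(names(fam_sizes))
      cum <- cumsum(as.integer(fam_sizes[fams]))
      k <- which.min(abs(cum - target))
      test_fams <- fams[seq_len(k)]
      is_test <- cohort$family_id %in% test_fams
      list(split_id = s,
           train_ids = cohort$subject_id[!is_test],
           test_ids = cohort$subject_id[is_test],
           seed = sseed)
    })
  })
}

# resolve x (matrix or provider function) for one split
resolve_features <- function(x, train_ids) {
  X <- if (is.function(x)) x(train_ids) else x
  as.matrix(X)
}

#' Fit and evaluate one split
#'
#' The inner loop of the evaluation: a standard scaler (per-feature mean/SD)
#' is fit on the training subjects only; hyperparameters are selected by
#' family-grouped inner cross-validation (maximizing inner R-squared or
#' accuracy); the model is refit on the full training set and scored on the
#' held-out test set. Continuous targets are standardized on the training set
#' before fitting and predictions are mapped back to original units.
#'
#' @param x feature matrix (`n x p`, rownames = subject ids) or a provider
#'   function of `train_ids` (see [gsp_feature_provider()]).
#' @param y target vector (numeric, or factor/character for classification),
#'   aligned with `cohort`.
#' @param split one element of [make_family_splits()].
#' @param model a [model_spec()] or model name.
#' @param cohort cohort data.frame (for family-grouped inner folds).
#' @param seed seed for the inner fold assignment.
#' @param r2_baseline `"test"` (default): R-squared computed against the
#'   test-set mean; `"train"`: against the training mean.
#' @return List: `metric` (test R-squared or accuracy), `params` (selected
#'   hyperparameters), `scaler`.
#' @export
fit_evaluate <- function(x, y, split, model, cohort, seed = 1L,
                         r2_baseline = c("test", "train")) {
  model <- as_model_spec(model)
  r2_baseline <- match.arg(r2_baseline)
  X <- resolve_features(x, split$train_ids)
  ids <- rownames(X) %||% cohort$subject_id
  tr_ix <- match(split$train_ids, ids)
  te_ix <- match(split$test_ids, ids)
  if (anyNA(tr_ix) || anyNA(te_ix)) stop("split ids missing from feature rows")
  used <- c(tr_ix, te_ix)
  Xu <- X[used, , drop = FALSE]
  if (any(!is.finite(Xu))) {
    bad <- ids[used][rowSums(!is.finite(Xu)) > 0]
    stop("non-finite features for subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  yy <- if (is.numeric(y)) y else as.character(y)
  ytr <- yy[match(split$train_ids, cohort$subject_id)]
  yte <- yy[match(split$test_ids, cohort$subject_id)]
  scaler <- fit_scaler(X[tr_ix, , drop = FALSE])
  Xtr <- apply_scaler(X[tr_ix, , drop = FALSE], scaler)
  Xte <- apply_scaler(X[te_ix, , drop = FALSE], scaler)
  fams <- cohort$family_id[match(split$train_ids, cohort$subject_id)]
  folds <- group_folds(fams, model$inner_folds, seed)
  if (model$task == "regression") {
    ymu <- mean(ytr); ysd <- stats::sd(ytr); if (ysd == 0) ysd <- 1
    ytr_s <- (ytr - ymu) / ysd
    params <- select_hyperparams(model, Xtr, ytr_s, folds)
    fit <- fit_final(model, Xtr, ytr_s, params)
    pred <- predict_final(model, fit, params, Xte) * ysd + ymu
    metric <- r_squared(yte, pred, r2_baseline, train_mean = ymu)
  } else {
    lev <- sort(unique(ytr))
    params <- select_hyperparams(model, Xtr, ytr, folds)
    fit <- fit_final(model, Xtr, ytr, params)
    pred <- predict_final(model, fit, params, Xte, levels = lev)
    metric <- mean(pred == yte)
  }
  list(metric = metric, params = params, scaler = scaler)
}

#' Permutation null distribution
#'
#' For each split and each of `n_perms` reshuffles, the target vector is
#' permuted uniformly across all subjects (split membership unchanged) and
#' the identical pipeline — scaling, inner CV, refit, test scoring — is
#' rerun, giving `n_splits x n_perms` null metrics.
#'
#' @inheritParams fit_evaluate
#' @param splits list from [make_family_splits()].
#' @param n_perms permutations per split (default 100).
#' @param seed seed for the permutation draws.
#' @return `n_splits x n_perms` matrix of null metrics.
#' @export
permutation_null <- function(x, y, splits, model, cohort, n_perms = 100L,
                             seed = 1L, r2_baseline = "test") {
  n <- nrow(cohort)
  out <- matrix(NA_real_, length(splits), n_perms)
  if (n_perms == 0L) return(out)
  for (s in seq_along(splits)) {
    split <- splits[[s]]
    inner_seed <- substream_seed(seed, paste0("inner_", split$split_id))
    for (p in seq_len(n_perms)) {
      perm <- with_seed(
        substream_seed(seed, paste0("perm_", split$split_id, "_", p)),
        sample.int(n))
      yp <- y[perm]
      out[s, p] <- fit_evaluate(x, yp, split, model, cohort,
                                seed = inner_seed,
                                r2_baseline = r2_baseline)$metric
    }
  }
  out
}

#' Permutation-based significance
#'
#' A feature predicts the target above chance when the mean of the real
#' test metrics strictly exceeds the 95th percentile of the permutation null
#' distribution. The reported p-value is
#' `(1 + #(null >= real mean)) / (1 + #null)`.
#'
#' @param real_metrics per-split test metrics.
#' @param null_metrics permutation metrics (any shape; flattened).
#' @param level percentile for the significance threshold (default 0.95).
#' @return List: `p_value`, `significant`, `threshold`, `real_mean`.
#' @export
significance <- function(real_metrics, null_metrics, level = 0.95) {
  real_metrics <- real_metrics[is.finite(real_metrics)]
  null_metrics <- as.numeric(null_metrics)
  null_metrics <- null_metrics[is.finite(null_metrics)]
  if (!length(real_metrics)) stop("no real metrics")
  if (!length(null_metrics))
    return(list(p_value = NA_real_, significant = NA,
                threshold = NA_real_, real_mean = mean(real_metrics)))
  rm_ <- mean(real_metrics)
  thr <- as.numeric(stats::quantile(null_metrics, level, type = 7))
  list(p_value = (1 + sum(null_metrics >= rm_)) / (1 + length(null_metrics)),
       significant = rm_ > thr, threshold = thr, real_mean = rm_)
}

#' Brain-behavior prediction with permutation significance
#'
#' The package's main fitting function. Evaluates how well one feature set
#' predicts one target: `n_splits` family-grouped train/test splits, each
#' scored with nested cross-validation (standard scaling and hyperparameter
#' selection inside the training set), plus a permutation null (`n_perms`
#' target reshuffles per split) and the 95th-percentile significance rule.
#'
#' @param x `n x p` feature matrix (rownames = subject ids) or a provider
#'   function of `train_ids` (see [gsp_feature_provider()]) for features
#'   that must be recomputed per training set.
#' @param y target: a numeric vector / factor aligned with `cohort`, or the
#'   name of a cohort column.
#' @param cohort data.frame with `subject_id` and `family_id`.
#' @param model model name or [model_spec()].
#' @param n_splits,test_frac,n_perms evaluation design (defaults 10, 0.15, 100).
#' @param seed master seed; splits, inner folds and permutations use named
#'   substreams of it.
#' @param splits optional precomputed splits (overrides `n_splits`/`seed`).
#' @param feature_name,target_name labels stored in the result.
#' @param r2_baseline see [fit_evaluate()].
#' @return Object of class `bb_prediction` with per-split metrics, the null
#'   matrix, p-value and significance verdict; see [summary.bb_prediction()].
#' @examples
#' spec <- cohort_spec(n_subjects = 60, n_regions = 12, n_sessions = 1,
#'                     frames_per_session = 60, seed = 7)
#' study <- simulate_study(spec,
#'   effects = effect_spec("score", "sd", signal_fraction = 0.5),
#'   features = "sd")
#' fit <- bb_predict(study$features$sd, "score", study$cohort,
#'                   model = "elastic_net", n_splits = 3, n_perms = 10,
#'                   seed = 1)
#' summary(fit)
#' @export
bb_predict <- function(x, y, cohort, model = "elastic_net",
                       n_splits = 10L, test_frac = 0.15, n_perms = 100L,
                       seed = 1L, splits = NULL,
                       feature_name = NULL, target_name = NULL,
                       r2_baseline = "test") {
  model <- as_model_spec(model)
  if (is.character(y) && length(y) == 1L) {
    target_name <- target_name %||% y
    y <- cohort[[y]]
    if (is.null(y)) stop("target column not found in cohort")
  }
  if (model$task == "classification" && is.numeric(y))
    stop("classification models need a factor/character target")
  if (model$task == "regression" && !is.numeric(y))
    stop("regression models need a numeric target")
  splits <- splits %||% make_family_splits(cohort, n_splits, test_frac,
                                           seed = substream_seed(seed, "splits"))
  per_split <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    per_split[[s]] <- fit_evaluate(
      x, y, splits[[s]], model, cohort,
      seed = substream_seed(seed, paste0("inner_", splits[[s]]$split_id)),
      r2_baseline = r2_baseline)
  }
  metrics <- vapply(per_split, `[[`, numeric(1), "metric")
  nulls <- permutation_null(x, y, splits, model, cohort, n_perms = n_perms,
                            seed = substream_seed(seed, "perms"),
                            r2_baseline = r2_baseline)
  sig <- if (n_perms > 0L) significance(metrics, nulls)
         else list(p_value = NA_real_, significant = NA,
                   threshold = NA_real_, real_mean = mean(metrics))
  structure(list(feature = feature_name %||% "feature",
                 target = target_name %||% "target",
                 model = model$name, task = model$task,
                 per_split_metric = metrics, null_metrics = nulls,
                 p_value = sig$p_value, significant = sig$significant,
                 null_threshold = sig$threshold,
                 details = per_split, splits = splits, seed = seed),
            class = "bb_prediction")
}

#' @export
print.bb_prediction <- function(x, ...) {
  mname <- if (x$task == "regression") "R^2" else "accuracy"
  cat(sprintf("Brain-behavior prediction: %s ~ %s [%s]\n",
              x$target, x$feature, x$model))
  cat(sprintf("  mean test %s = %.3f over %d splits\n", mname,
              mean(x$per_split_metric), length(x$per_split_metric)))
  if (!is.na(x$p_value))
    cat(sprintf("  permutation p = %.4g (null 95th pct = %.3f) -> %s\n",
                x$p_value, x$null_threshold,
                if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Summary statistics of a prediction result
#'
#' One row per result: mean, SD, median, first and third quartile (type-7
#' quantiles) of the per-split test metric, the permutation p-value and the
#' significance verdict.
#'
#' @param object a `bb_prediction`.
#' @param ... unused.
#' @return A one-row data.frame.
#' @export
summary.bb_prediction <- function(object, ...) {
  m <- object$per_split_metric
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), type = 7)
  data.frame(feature = object$feature, target = object$target,
             model = object$model,
             mean = mean(m), sd = stats::sd(m),
             median = q[[2L]], q1 = q[[1L]], q3 = q[[3L]],
             p_value = object$p_value,
             significant = object$significant,
             row.names = NULL)
}

#' @export
plot.bb_prediction <- function(x, ...) {
  mname <- if (x$task == "regression") "R^2" else "accuracy"
  nulls <- as.numeric(x$null_metrics)
  nulls <- nulls[is.finite(nulls)]
  if (length(nulls)) {
    graphics::hist(nulls, breaks = 30, col = "grey85", border = "white",
                   main = sprintf("%s ~ %s [%s]", x$target, x$feature, x$model),
                   xlab = mname,
                   xlim = range(c(nulls, x$per_split_metric)))
    graphics::abline(v = x$null_threshold, lty = 2)
  } else {
    graphics::plot(x$per_split_metric, xlab = "split", ylab = mname,
                   main = sprintf("%s ~ %s [%s]", x$target, x$feature, x$model))
  }
  graphics::abline(v = mean(x$per_split_metric), col = "firebrick", lwd = 2)
  graphics::rug(x$per_split_metric, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Tabulate a set of prediction results
#'
#' Stacks [summary.bb_prediction()] rows for several results into one table
#' (the layout used to report feature-by-target-by-model comparisons).
#'
#' @param results list of `bb_prediction` objects (may be empty).
#' @return data.frame with one row per result.
#' @export
summarize_results <- function(results) {
  if (!length(results))
    return(data.frame(feature = character(), target = character(),
                      model = character(), mean = numeric(), sd = numeric(),
                      median = numeric(), q1 = numeric(), q3 = numeric(),
                      p_value = numeric(), significant = logical()))
  do.call(rbind, lapply(results, summary))
}
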